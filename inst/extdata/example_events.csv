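learner_id,task_index,completion_time_days
alice,1,2.5
alice,2,4.1
alice,3,6.0
alice,4,9.2
bob,1,5.0
bob,2,5.1
bob,3,5.1
bob,4,11.8
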