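quantity,value
lab_recorded_flights,15208
lab_valid_flights,14067
lab_test_set_flights,1000
bags_collected,53
bags_collected_trial1,32
bags_collected_trial2,21
bags_excluded_depredation,7
bags_excluded_connectivity,2
cycles_analyzed_trial1,29
cycles_analyzed_trial2,15
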