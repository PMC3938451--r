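group,stratum,positive,total
paroxysmal,first_hour_sensitivity,37,70
paroxysmal_sinus_first_hour,first_hour_sensitivity,23,54
paroxysmal_holter_negative,first_hour_sensitivity,19,47
post_episode,hour_1,7,9
post_episode,hour_2,5,7
post_episode,hour_3,3,7
paroxysmal,holter_detection_full,19,70
paroxysmal,holter_detection_first_hour,13,70
chronic,holter_detection_full,16,19
chronic,holter_detection_first_hour,14,19
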