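group,stratum,positive,total
paroxysmal_holter_negative,first_hour,19,47
healthy,first_hour,99,100
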