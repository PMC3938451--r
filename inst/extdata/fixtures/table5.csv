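group,stratum,positive,total
af_confirmed,af_episode_snips,500,504
healthy,af_episode_snips,2797,2821
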