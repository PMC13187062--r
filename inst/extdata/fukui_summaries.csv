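specimen_id,n_on,mean_onar,sd_onar,mean_har,sd_har
FK-B-002,3,13743.9,2766.0,490.5,190.6
FK-B-003,21,18174.1,5226.5,478.7,186.2
FK-B-006,6,15936.1,3689.1,500.5,370.7
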