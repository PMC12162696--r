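method,measure,pre_mean,pre_sd,post_mean,post_sd,change_mean,change_sd
AI1,volume_ml,187.35,41.76,169.28,39.64,18.07,12.53
AI2,volume_ml,189.17,41.63,171.18,39.59,17.98,12.46
AI1,percentage,47.84,10.77,43.17,9.84,4.67,3.25
AI2,percentage,48.30,10.71,43.66,9.80,4.64,3.23
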