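study_id,effect,n_eff,s2,df
trial1,0.86,61.30,19.94,243
trial2,NA,81.06,24.96,322
trial3,NA,69.24,8.56,275
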