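rater,specialty,willingness,quality
doctor01,9,1,10
doctor02,7,3,10
doctor03,8,2,10
doctor04,8,2,10
doctor05,8,2,10
doctor06,8,2,10
doctor07,8,2,10
doctor08,8,2,10
doctor09,9,3,10
doctor10,7,1,10
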