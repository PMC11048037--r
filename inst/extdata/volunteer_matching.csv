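lighting,ambient_cd_m2,trial,volunteer,age,matched,note
bright,235,1,NO.1,25,1,matched
bright,235,2,NO.2,33,1,matched
bright,235,3,NO.3,35,0,nearsighted; good match without glasses but stimulus slightly stronger with glasses
bright,235,4,NO.4,42,1,matched
bright,235,5,NO.5,48,1,matched
dim,0.025,1,NO.1,25,1,matched
dim,0.025,2,NO.2,33,1,matched
dim,0.025,3,NO.3,35,1,matched
dim,0.025,4,NO.4,42,1,matched
dim,0.025,5,NO.5,48,1,matched
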