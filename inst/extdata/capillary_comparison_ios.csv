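level,deficient,insufficient,sufficient
deficient,12,1,0
insufficient,0,6,0
sufficient,0,0,3
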