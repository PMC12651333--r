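level,deficient,insufficient,sufficient
deficient,14,1,0
insufficient,1,38,1
sufficient,0,0,45
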