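sample,e12_votes,e12_applications,e3_votes,e3_applications,e4_votes,e4_applications,stage_label
RODM 001,0,12,0,10,9,9,late
RODM 008,0,8,11,11,5,7,late
RODM 011,0,7,0,13,11,11,late
RODM 015,0,7,0,6,11,11,late
RODM 032,0,7,0,10,8,8,early
RODM 036,0,11,0,7,11,11,late
RODM 037,0,9,0,10,7,7,late
RODM 048,12,13,12,12,9,9,early
RODM 061,8,8,10,10,5,13,early
RODM 065,5,6,6,9,8,8,late
RODM 066,0,8,0,8,9,11,early
RODM 071,8,9,7,7,15,16,early
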