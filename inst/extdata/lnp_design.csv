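run_id,DSPC,SM-102,cholesterol,DMG-PEG2000,is_validation
M01,19,65,15,1,FALSE
M02,5,35,50,10,FALSE
M03,18.3,35.9,35.8,10,FALSE
M04,5,53,38,4,FALSE
M05,40,15,35,10,FALSE
M06,40,29.5,29.5,1,FALSE
M07,14.9,51.2,26.2,7.7,FALSE
M08,5,65,29,1,FALSE
M09,23,15,58,4,FALSE
M10,8.3,65,16.7,10,FALSE
M11,40,39.5,15,5.5,FALSE
M12,5,20,65,10,FALSE
M13,29.9,40.7,26.2,3.2,FALSE
M14,5,29,65,1,FALSE
M15,24.7,26.2,45.9,3.2,FALSE
MS,10,50,38.5,1.5,TRUE
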