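study_id,arm,term,count,author_serious
syn01,treatment,synovitis,1,TRUE
syn01,treatment,knee pain,6,FALSE
syn01,treatment,headache,4,FALSE
syn01,control,erythema,3,FALSE
syn01,control,herpes zoster,1,TRUE
syn02,treatment,cancer,4,TRUE
syn02,treatment,joint sprain,2,FALSE
syn02,treatment,septic arthritis,1,TRUE
syn02,control,myocardial infarction,1,FALSE
syn02,control,knee pain,5,FALSE
syn03,treatment,flare,2,FALSE
syn03,control,flare,3,FALSE
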