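substrate,fuc,ara,rha,gal,glc,xyl,man,gala,glca,dac,dm,synthetic
apple,6,157,110,281,237,51,5,3875,8,2,69,FALSE
citrus,4,98,152,478,71,15,4,4195,5,1,53,FALSE
sugarbeet,5,512,264,532,30,11,3,2940,33,19,56,FALSE
pga,0,0,0,0,0,0,0,5208,0,0,0,TRUE
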