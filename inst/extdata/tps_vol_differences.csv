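source,tps,r_cm,pct_dose,diff_pp
6711,VariSeed,1,100.0,0.3
6711,VariSeed,2,20.5,0.2
6711,VariSeed,3,7.1,0.3
6711,VariSeed,4,3.1,0.5
6711,VariSeed,5,1.5,0.6
6711,BrachyVision,1,100.0,0.8
6711,BrachyVision,2,20.5,0.9
6711,BrachyVision,3,7.1,2.0
6711,BrachyVision,4,3.1,3.6
6711,BrachyVision,5,1.5,-4.3
6711,Pinnacle,1,100.0,0.1
6711,Pinnacle,2,20.5,-0.1
6711,Pinnacle,3,7.1,0.5
6711,Pinnacle,4,3.1,0.2
6711,Pinnacle,5,1.5,0.1
6711,MIM,1,100.0,0.3
6711,MIM,2,20.5,-0.1
6711,MIM,3,7.1,0.8
6711,MIM,4,3.1,4.9
6711,MIM,5,1.5,-2.2
VS2000,BrachyVision,1,100.0,0.8
VS2000,BrachyVision,2,25.5,0.8
VS2000,BrachyVision,3,11.4,0.8
VS2000,BrachyVision,4,6.4,0.8
VS2000,BrachyVision,5,4.1,-0.2
VS2000,Pinnacle,1,100.0,0.3
VS2000,Pinnacle,2,25.5,-0.1
VS2000,Pinnacle,3,11.4,0.1
VS2000,Pinnacle,4,6.4,-0.1
VS2000,Pinnacle,5,4.1,-0.4
mHDRv2,Pinnacle,1,100.0,0.1
mHDRv2,Pinnacle,2,20.5,0.1
mHDRv2,Pinnacle,3,7.1,0.1
mHDRv2,Pinnacle,4,3.1,0.8
mHDRv2,Pinnacle,5,1.5,0.3
mHDRv2,Oncentra,1,100.0,-0.6
mHDRv2,Oncentra,2,20.5,-0.4
mHDRv2,Oncentra,3,7.1,-0.3
mHDRv2,Oncentra,4,3.1,-0.2
mHDRv2,Oncentra,5,1.5,1.0
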