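pld,1.0
plan,FIXTURE-1L,tsd_cm,10,range_shifter,Y,prescription_gy,5
layer,1,energy_mev,100.5,nspots,2,cum_mu,1.75
spot,-3,0,0.25
spot,3,0,1.5
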