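year,model,n_nights,alpha0,alpha0_lwr,alpha0_upr,alpha1,alpha1_lwr,alpha1_upr,alpha2,alpha2_lwr,alpha2_upr,alpha3,alpha3_lwr,alpha3_upr,mortality,mortality_lwr,mortality_upr,corrected,corrected_lwr,corrected_upr
2007,one_level,473,-2.7,-3.2,-2.1,0.4,0.1,0.7,-0.2,-0.9,0.3,-0.2,-0.6,0.2,37,28,49,38,27,59
2007,three_level,473,-2.3,-2.9,-1.7,0.5,0.1,0.9,0.4,-0.4,1.3,-0.7,-2.0,0.0,38,29,49,38,27,59
2008,one_level,1225,-3.5,-4.1,-3.0,0.4,0.1,0.7,-1.8,-3.0,-0.8,-0.8,-1.6,-0.3,56,46,70,57,42,89
2008,three_level,1225,-4.1,-5.3,-3.3,0.5,0.2,0.8,-2.9,-5.6,-1.2,-1.3,-2.6,-0.4,57,46,71,57,42,89
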