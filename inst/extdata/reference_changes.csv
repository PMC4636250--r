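scenario,variant,pathway,ref_mean,ref_sd,note
fig1b_top,400-DBS-100,medial,23.0,2.3,reference simulated LTP; canonical configuration (3 runs)
fig1b_top,400-DBS-100,lateral,-38.5,1.3,reference simulated LTD; canonical configuration (3 runs)
fig1b_mid,400-DBS-60,medial,45.3,4.4,reference simulated LTP; canonical configuration (3 runs)
fig1b_mid,400-DBS-60,lateral,-30.6,1.5,reference simulated LTD; canonical configuration (3 runs)
fig2a,100-TBS-60,medial,5.3,0.3,reference simulated LTP; canonical configuration (3 runs)
fig2a,100-TBS-60,lateral,-6.5,0.3,reference simulated LTD; canonical configuration (3 runs)
fig2b,400-TBS-60,medial,25.0,2.0,reference simulated LTP; canonical configuration (3 runs)
fig2b,400-TBS-60,lateral,-20.7,1.6,reference simulated LTD; canonical configuration (3 runs)
fig3,400-DBS,medial,45.3,4.4,reference simulated LTP; canonical configuration (3 runs)
fig3,400-DBS,lateral,-30.6,1.5,reference simulated LTD; canonical configuration (3 runs)
fig3,100-TBS,medial,5.3,0.3,reference simulated LTP; canonical configuration (3 runs)
fig3,100-TBS,lateral,-6.5,0.3,reference simulated LTD; canonical configuration (3 runs)
fig3,400-TBS,medial,25.0,2.0,reference simulated LTP; canonical configuration (3 runs)
fig3,400-TBS,lateral,-20.7,1.6,reference simulated LTD; canonical configuration (3 runs)
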