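horizon,sex,test,sens,spec,dor_printed,dor_exact
5,F,bmd,47.8,92.9,12.0,TRUE
5,F,frax,75.9,79.1,11.9,TRUE
5,F,bct,81.4,80.0,17.4,FALSE
5,M,bmd,26.8,98.6,25.4,FALSE
5,M,frax,58.1,89.4,11.7,TRUE
5,M,bct,66.9,92.2,23.9,TRUE
2,F,bmd,52.2,88.3,8.2,TRUE
2,F,frax,79.6,72.1,10.1,TRUE
2,F,bct,85.3,73.0,15.7,TRUE
2,M,bmd,30.6,97.1,14.5,FALSE
2,M,frax,59.2,84.7,8.0,TRUE
2,M,bct,73.2,87.3,18.7,FALSE
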