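stratum,pop_fr,test,threshold,direction,test_pr,sens,ppv_printed,prev_printed,class_printed,ppv_exact,prev_exact
women_ge65,5.8,frax,3.0,ge,34.6,75.9,12.7,23,high,TRUE,TRUE
women_ge65,5.8,frax,4.5,ge,23.5,62.7,15.4,19,very_high,FALSE,TRUE
women_ge65,5.8,bmd,-2.5,le,18.0,47.8,15.3,15,high,FALSE,TRUE
women_ge65,5.8,bct,75,ge,34.5,81.4,13.6,25,high,FALSE,TRUE
women_ge65,5.8,bct,80,ge,29.8,76.3,14.8,23,high,FALSE,TRUE
women_ge65,5.8,bct,85,ge,24.4,70.4,16.6,22,very_high,FALSE,TRUE
women_ge65,5.8,bct,90,ge,18.5,62.1,19.4,19,very_high,FALSE,TRUE
women_ge65,5.8,bct,95,ge,12.4,48.2,22.4,15,very_high,FALSE,TRUE
women_ge70,8.3,frax,3.0,ge,48.9,82.8,14.1,36,high,TRUE,TRUE
women_ge70,8.3,frax,4.5,ge,34.3,69.6,16.9,31,very_high,FALSE,TRUE
women_ge70,8.3,bmd,-2.5,le,24.2,51.7,17.8,23,very_high,FALSE,TRUE
women_ge70,8.3,bct,75,ge,48.8,86.4,14.7,38,high,TRUE,TRUE
women_ge70,8.3,bct,80,ge,43.0,81.7,15.8,36,high,TRUE,TRUE
women_ge70,8.3,bct,85,ge,36.0,76.8,17.7,34,very_high,TRUE,TRUE
women_ge70,8.3,bct,90,ge,27.8,68.2,20.4,30,very_high,TRUE,TRUE
women_ge70,8.3,bct,95,ge,18.9,53.4,23.5,24,very_high,TRUE,FALSE
men_ge65,3.4,frax,3.0,ge,20.0,58.1,9.8,10,high,FALSE,TRUE
men_ge65,3.4,frax,4.5,ge,9.7,38.8,13.4,7,very_high,FALSE,TRUE
men_ge65,3.4,bmd,-2.5,le,6.2,26.8,14.5,5,very_high,FALSE,TRUE
men_ge65,3.4,bct,75,ge,19.9,66.9,11.3,12,high,FALSE,TRUE
men_ge65,3.4,bct,80,ge,16.9,61.6,12.2,11,high,FALSE,TRUE
men_ge65,3.4,bct,85,ge,13.8,51.3,12.5,9,high,FALSE,TRUE
men_ge65,3.4,bct,90,ge,10.3,42.5,13.9,8,very_high,FALSE,TRUE
men_ge65,3.4,bct,95,ge,5.7,26.5,15.6,5,very_high,FALSE,TRUE
men_ge70,4.5,frax,3.0,ge,30.0,65.0,9.8,16,high,TRUE,TRUE
men_ge70,4.5,frax,4.5,ge,14.6,43.5,13.5,10,very_high,FALSE,TRUE
men_ge70,4.5,bmd,-2.5,le,8.8,28.5,14.8,7,very_high,FALSE,TRUE
men_ge70,4.5,bct,75,ge,29.7,73.1,11.2,18,high,FALSE,FALSE
men_ge70,4.5,bct,80,ge,25.4,68.2,12.2,16,high,FALSE,TRUE
men_ge70,4.5,bct,85,ge,21.1,57.9,12.5,14,high,FALSE,TRUE
men_ge70,4.5,bct,90,ge,16.1,48.6,13.7,12,very_high,FALSE,TRUE
men_ge70,4.5,bct,95,ge,8.8,38.4,19.7,9,very_high,FALSE,TRUE
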