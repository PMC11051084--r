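study,method,comparison,period,interruptions,interactions
1,mean_2sd,hypothesis,pre_covid,6107869,301995418
1,mean_2sd,hypothesis,peak_covid,830424,41255775
1,mean_2sd,hypothesis,post_peak,13129965,652436314
1,mean_2sd,seasonality,apr_may_2019,745691,39499072
1,mean_2sd,seasonality,apr_may_2020,830424,41255775
1,mean_2sd,seasonality,apr_may_2021,732269,38079051
1,mean_2sd,seasonality,apr_may_2022,641015,33944478
2,speed_adjusted,hypothesis,pre_covid,8289573,301995418
2,speed_adjusted,hypothesis,peak_covid,1128205,41255775
2,speed_adjusted,hypothesis,post_peak,19020378,652436314
2,speed_adjusted,seasonality,apr_may_2019,980407,39499072
2,speed_adjusted,seasonality,apr_may_2020,1128205,41255775
2,speed_adjusted,seasonality,apr_may_2021,1042978,38079051
2,speed_adjusted,seasonality,apr_may_2022,914577,33944478
3,speed_adjusted_restricted,hypothesis,pre_covid,636550,29865657
3,speed_adjusted_restricted,hypothesis,peak_covid,81864,3840171
3,speed_adjusted_restricted,hypothesis,post_peak,1375571,62982490
3,speed_adjusted_restricted,seasonality,apr_may_2019,80077,4173068
3,speed_adjusted_restricted,seasonality,apr_may_2020,81864,3840171
3,speed_adjusted_restricted,seasonality,apr_may_2021,67116,3302522
3,speed_adjusted_restricted,seasonality,apr_may_2022,63348,3168362
4,modified_z,hypothesis,pre_covid,3902034,301995418
4,modified_z,hypothesis,peak_covid,541229,41255775
4,modified_z,hypothesis,post_peak,7615344,652436314
4,modified_z,seasonality,apr_may_2019,542901,39499072
4,modified_z,seasonality,apr_may_2020,541229,41255775
4,modified_z,seasonality,apr_may_2021,450813,38079051
4,modified_z,seasonality,apr_may_2022,395661,33944478
5,long_interruption,hypothesis,pre_covid,454676,123897496
5,long_interruption,hypothesis,peak_covid,118497,41255775
5,long_interruption,hypothesis,post_peak,2297449,652436314
5,long_interruption,seasonality,apr_may_2020,118497,41255775
5,long_interruption,seasonality,apr_may_2021,118871,38079051
5,long_interruption,seasonality,apr_may_2022,108245,33944478
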