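metric,group,value,units,source
livebirth_rate,all,54.3,per_1000_women_15_44,ONS England 2021
stillbirth_rate,all,4.1,per_1000_deliveries,ONS England 2021
termination_share,all,8.8,percent_of_pregnancies,CPRD pregnancy register
stillbirth_share,all,0.4,percent_of_deliveries,CPRD Gold
stillbirth_share,all,0.3,percent_of_deliveries,CPRD Aurum
miscarriage_share,all,9.1,percent_of_pregnancies,CPRD Gold
miscarriage_share,all,8.4,percent_of_pregnancies,CPRD Aurum
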