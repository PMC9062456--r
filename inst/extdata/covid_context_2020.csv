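country,group,unit_type,n_units,cum_cases_per_100k,mean_stringency,in_group_average
Burkina Faso,West Africa,Districts,70,31.2,43.6,TRUE
Cote d'Ivoire,West Africa,Districts,113,83.1,44.6,TRUE
Ghana,West Africa,Districts,260,172.6,48.5,TRUE
Liberia,West Africa,Counties,15,34.7,65.1,TRUE
Mali,West Africa,Districts,75,34.0,54.3,TRUE
Niger,West Africa,Districts,72,13.2,32.4,TRUE
Nigeria,West Africa,States,37,41.4,63.1,TRUE
Ethiopia,Eastern Africa,Regions,12,105.4,65.9,TRUE
Kenya,Eastern Africa,Counties,47,175.4,66.2,TRUE
Tanzania,Eastern Africa,District councils,184,0.8,,FALSE
Uganda,Eastern Africa,Districts,136,74.7,74.9,TRUE
Zambia,Eastern Africa,Districts,116,109.5,46.1,TRUE
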