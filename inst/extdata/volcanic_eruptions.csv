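# Major volcanic eruptions (VEI >= 4) associated with Northern-Hemisphere cold anomalies
year,name,vei
536,Unknown (536 event),7
541,Ilopango/El Chichon,7
1257,Samalas,7
1812,La Soufriere,4
1814,Mayon,4
1815,Tambora,7
1822,Galunggung,5
1835,Cosiguina,5
1883,Krakatoa,6
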