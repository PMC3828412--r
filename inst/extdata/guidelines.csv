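compound,source,effect_class,value,units
formaldehyde,GB/T 18883-2002,iaq_standard,0.10,mg/m3
benzene,GB/T 18883-2002,iaq_standard,0.11,mg/m3
formaldehyde,OEHHA,acute,55,ug/m3
benzene,OEHHA,acute,1300,ug/m3
formaldehyde,OEHHA,chronic,9,ug/m3
benzene,OEHHA,chronic,60,ug/m3
benzene,U.S. EPA IRIS,chronic,30,ug/m3
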