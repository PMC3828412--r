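compound,source,variant,iur,units
formaldehyde,U.S. EPA IRIS,default,1.3e-5,per_ug_m3
benzene,U.S. EPA IRIS,default,7.8e-6,per_ug_m3
benzene,U.S. EPA IRIS,alternate,2.2e-6,per_ug_m3
formaldehyde,OEHHA,default,6.0e-6,per_ug_m3
benzene,OEHHA,default,2.9e-5,per_ug_m3
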