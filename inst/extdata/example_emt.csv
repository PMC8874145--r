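"plate","well","cd","clone","gene","vendor","titer_volume_ul"
"P1","A1","CD11b","ICRF44","ITGAM","BioLegend",2.5
"P1","A2","CD31","MEM-05","PECAM1","Exbio",2.5
"P1","A3","CD38","HIT2","CD38","Exbio",2.5
"P1","A4","CD40","5C3","CD40","Exbio",2.5
"P1","A5","CD3","UCHT1","CD3E","Exbio",2.5
"P1","A6","CD3","SK7","CD3E","Exbio",2.5
"P1","A7","CD3","TB3","CD3E","Exbio",2.5
"P1","A8","CD3","MEM-57","CD3E","Exbio",2.5
"P1","A9","CD19","LT19","CD19","Exbio",2.5
"P1","A10","CD45","2D1","PTPRC","Exbio",2.5
"P1","A11","CD56","HCD56","NCAM1","Exbio",2.5
"P1","A12","FMO","","","",0
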