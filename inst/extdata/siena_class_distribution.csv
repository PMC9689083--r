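patient_id,file_names,normal_s,seizure_s,seizure_ratio
1,"PN00-1, PN00-2, PN00-3, PN00-4, PN00-5",11581,315,0.0264
2,"PN01-1",12000,55,0.0045
3,"PN03-2",11581,74,0.0063
4,"PN05-2, PN05-3, PN05-4",21727,107,0.0049
5,"PN06-1, PN06-4, PN06-5",22662,147,0.0064
6,"PN07-1",12000,63,0.0052
7,"PN09-1",8233,81,0.0097
8,"PN10-1",9982,70,0.0069
9,"PN11-1",8677,56,0.0064
10,"PN12-1",9774,64,0.0065
11,"PN13-1",9355,49,0.0052
12,"PN14-1",7868,28,0.0035
13,"PN16-1",8270,124,0.0147
14,"PN17-1",9277,71,0.0075
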