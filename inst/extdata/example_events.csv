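patient_id,date,code_system,code,hospitalization_flag,death_flag
P001,2019-12-30,demographic,age:74,0,0
P001,2019-12-30,demographic,sex:F,0,0
P001,2019-12-30,demographic,race:White,0,0
P001,2019-11-02,diagnosis,331.0,0,0
P001,2019-12-10,diagnosis,290.1,0,0
P001,2019-12-15,drug,00093-7180,0,0
P001,2020-01-02,drug,00123-4567,0,0
P001,2020-01-20,drug,00123-4567,0,0
P001,2020-02-05,diagnosis,428.0,1,0
P002,2020-02-28,demographic,age:81,0,0
P002,2020-02-28,demographic,sex:M,0,0
P002,2020-02-28,demographic,race:Black,0,0
P002,2020-01-15,diagnosis,331.0,0,0
P002,2020-02-20,diagnosis,272.4,0,0
P002,2020-03-01,drug,00123-4567,0,0
P002,2020-03-25,diagnosis,401.9,0,0
P003,2020-01-10,demographic,age:69,0,0
P003,2020-01-10,demographic,sex:F,0,0
P003,2020-01-10,demographic,race:White,0,0
P003,2020-01-05,diagnosis,272.4,0,0
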