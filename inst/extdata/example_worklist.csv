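id,sex,age_years,height_cm,weight_kg,target_count_rate_kcps,scheduled_time,actual_time
pt001,f,61,168.5,73.5,1.7,2018-11-05T09:00:00,2018-11-05T09:10:00
pt002,m,45,181,88,1.7,2018-11-05T09:20:00,2018-11-05T09:20:00
pt003,f,70,160,55,1.7,2018-11-05T09:40:00,2018-11-05T09:35:00
pt004,m,58,,80,1.7,2018-11-05T10:00:00,
pt005,f,33,158,48,1.0,2018-11-05T10:20:00,2018-11-05T10:30:00
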