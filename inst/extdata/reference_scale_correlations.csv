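item_id,label,r_depression,r_anxiety
total,somatic total score,0.798,0.717
S1,fatigue,0.573,0.531
S2,forgetfulness,0.504,0.468
S3,sighing,0.598,0.575
S4,stool abnormity,0.510,0.423
S5,dyssomnia,0.691,0.551
S6,weakness,0.599,0.536
S7,pant,0.519,0.459
S8,stomach distension,0.500,0.474
S9,chest distress,0.588,0.539
S10,palpitation,0.509,0.487
S11,soreness of waist,0.539,0.491
S12,thirst,0.481,0.478
S13,sweating,0.492,0.489
S14,lumbago,0.452,0.417
S15,alopecia,0.368,0.351
S16,eating disorder,0.455,0.381
S17,bellyache,0.388,0.370
S18,xerophthalmia,0.388,0.344
S19,headache,0.489,0.418
S20,dizzy,0.461,0.426
S21,cold,0.310,0.314
S22,fever,0.332,0.296
S23,cough,0.290,0.263
S24,foreign body sensation,0.308,0.278
S25,anal burning,0.375,0.303
S26,abdominal distension,0.456,0.425
S27,frequent micturition,0.399,0.389
S28,nausea,0.405,0.382
S29,tinnitus,0.323,0.261
S30,hiccup,0.409,0.390
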