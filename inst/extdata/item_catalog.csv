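item_id,label,scale,community
S1,fatigue,somatic,somatic
S2,forgetfulness,somatic,somatic
S3,sighing,somatic,somatic
S4,stool abnormity,somatic,somatic
S5,dyssomnia,somatic,somatic
S6,weakness,somatic,somatic
S7,pant,somatic,somatic
S8,stomach distension,somatic,somatic
S9,chest distress,somatic,somatic
S10,palpitation,somatic,somatic
S11,soreness of waist,somatic,somatic
S12,thirst,somatic,somatic
S13,sweating,somatic,somatic
S14,lumbago,somatic,somatic
S15,alopecia,somatic,somatic
S16,eating disorder,somatic,somatic
S17,bellyache,somatic,somatic
S18,xerophthalmia,somatic,somatic
S19,headache,somatic,somatic
S20,dizzy,somatic,somatic
S21,cold,somatic,somatic
S22,fever,somatic,somatic
S23,cough,somatic,somatic
S24,foreign body sensation,somatic,somatic
S25,anal burning,somatic,somatic
S26,abdominal distension,somatic,somatic
S27,frequent micturition,somatic,somatic
S28,nausea,somatic,somatic
S29,tinnitus,somatic,somatic
S30,hiccup,somatic,somatic
P1,little interest or pleasure in doing things,PHQ2,anxiety_depression
P2,"feeling down, depressed, or hopeless",PHQ2,anxiety_depression
G1,"feeling nervous, anxious or eager",GAD7,anxiety_depression
G2,uncontrollable worries,GAD7,anxiety_depression
G3,worrying too much about things,GAD7,anxiety_depression
G4,trouble relaxing,GAD7,anxiety_depression
G5,unable to sit still due to restlessness,GAD7,anxiety_depression
G6,easily annoyed or irritable,GAD7,anxiety_depression
G7,feeling afraid as if something awful might happen,GAD7,anxiety_depression
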