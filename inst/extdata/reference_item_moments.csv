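item_id,label,community,mean,sd
S1,fatigue,somatic,1.45,1.06
S2,forgetfulness,somatic,1.20,1.03
S3,sighing,somatic,1.00,0.93
S4,stool abnormity,somatic,0.67,0.84
S5,dyssomnia,somatic,0.69,0.88
S6,weakness,somatic,0.66,0.94
S7,pant,somatic,0.62,0.83
S8,stomach distension,somatic,0.54,0.79
S9,chest distress,somatic,0.51,0.79
S10,palpitation,somatic,0.45,0.69
S11,soreness of waist,somatic,0.49,0.77
P1,little interest or pleasure in doing things,anxiety_depression,0.59,0.70
P2,"feeling down, depressed, or hopeless",anxiety_depression,0.66,0.65
G1,"feeling nervous, anxious or eager",anxiety_depression,0.80,0.69
G2,uncontrollable worries,anxiety_depression,0.56,0.81
G3,worrying too much about things,anxiety_depression,0.65,0.83
G4,trouble relaxing,anxiety_depression,0.60,0.83
G5,unable to sit still due to restlessness,anxiety_depression,0.37,0.69
G6,easily annoyed or irritable,anxiety_depression,0.53,0.77
G7,feeling afraid as if something awful might happen,anxiety_depression,0.37,0.68
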