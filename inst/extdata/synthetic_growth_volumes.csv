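"tumor_id","t_days","volume_mm3"
"sim_001",0,0.28265
"sim_001",21,0.37262
"sim_001",42,0.55522
"sim_001",70,0.99206
"sim_002",0,0.27117
"sim_002",21,0.37561
"sim_002",42,0.48216
"sim_002",70,0.71737
"sim_003",0,0.28756
"sim_003",21,0.3887
"sim_003",42,0.5391
"sim_003",70,0.921
"sim_004",0,0.26402
"sim_004",21,0.43675
"sim_004",42,0.56307
"sim_004",70,0.79196
"sim_005",0,0.34715
"sim_005",21,0.45517
"sim_005",42,0.5238
"sim_005",70,0.7954
"sim_006",0,0.29992
"sim_006",21,0.42394
"sim_006",42,0.50796
"sim_006",70,0.91022
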