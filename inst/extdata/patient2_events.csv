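day,category,procedure
0,TreatmentStart,Treatment Start
53,Action,Radiation Therapy
168,Status,No Evidence of Disease (NED)
830,Status,Relapse/Recurrence
845,Action,Surgery
869,Status,Progression
888,Action,Chemotherapy
930,Status,Stable Disease
960,Action,Surgery
1027,Action,Radiation Therapy
1113,Status,No Evidence of Disease (NED)
2300,Status,Progression
2339,Action,Surgery
2489,Action,Other Therapies
2540,Status,Partial Remission/Partial or Mixed Response
2582,Action,Other Therapies
2624,Status,Stable Disease
2637,Action,Surgery
2666,Action,Other Therapies
2708,Status,Stable Disease
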