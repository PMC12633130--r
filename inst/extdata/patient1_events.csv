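day,category,procedure
0,TreatmentStart,Treatment Start
28,Action,Chemotherapy/Biotherapy/Investigational/SMI
33,Action,Radiation Therapy
517,Status,Relapse/Recurrence
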