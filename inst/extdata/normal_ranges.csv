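feature,kind,unit,low,high,required
sbp,vital,mmHg,90,120,TRUE
dbp,vital,mmHg,60,80,TRUE
heart_rate,vital,bpm,60,100,TRUE
pao2,vital,mmHg,75,100,FALSE
resp_rate,vital,breaths/min,12,20,TRUE
spo2,vital,%,95,100,TRUE
temperature,vital,degC,36.5,37.5,TRUE
glucose,lab,mg/dL,70,140,FALSE
bilirubin,lab,mg/dL,0.1,1.2,FALSE
wbc,lab,1e9/L,4,12,TRUE
rbc,lab,1e12/L,4.2,5.9,FALSE
lymphocytes,lab,%,20,40,TRUE
alt,lab,U/L,7,56,FALSE
inr,lab,ratio,0.8,1.2,FALSE
ph,lab,pH,7.35,7.45,FALSE
bun,lab,mg/dL,7,20,FALSE
creatinine,lab,mg/dL,0.6,1.2,TRUE
platelets,lab,1e9/L,150,400,FALSE
neutrophils,lab,%,40,70,TRUE
monocytes,lab,%,2,8,FALSE
hematocrit,lab,%,36,50,FALSE
lactate,lab,mmol/L,0.5,2.0,FALSE
ast,lab,U/L,10,40,FALSE
sirs,computed,score,0,4,FALSE
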