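smq_code,smq_name,scope,parent_code,pt_name
20000049,Cardiac arrhythmias,narrow,,Atrial fibrillation
20000049,Cardiac arrhythmias,narrow,,Ventricular tachycardia
20000049,Cardiac arrhythmias,narrow,,Arrhythmia
20000004,Cardiac failure,narrow,,Cardiac failure
20000004,Cardiac failure,narrow,,Cardiac failure congestive
20000004,Cardiac failure,narrow,,Cardiogenic shock
20000150,Cardiomyopathy,narrow,,Cardiomyopathy
20000150,Cardiomyopathy,narrow,,Ejection fraction decreased
20000081,Embolic and thrombotic events,narrow,,Embolism
20000147,Hypertension,narrow,,Hypertension
20000147,Hypertension,narrow,,Blood pressure increased
20000147,Hypertension,narrow,,Hypertensive crisis
20000043,Ischaemic heart disease,narrow,,Angina pectoris
20000043,Ischaemic heart disease,narrow,,Coronary artery occlusion
20000239,Noninfectious myocarditis/pericarditis,narrow,,Pericarditis
20000239,Noninfectious myocarditis/pericarditis,narrow,,Myocarditis
20000130,Pulmonary hypertension,narrow,,Pulmonary hypertension
20000001,Torsade de pointes/QT prolongation,narrow,,Torsade de pointes
20000001,Torsade de pointes/QT prolongation,narrow,,Electrocardiogram QT prolonged
20000082,"Embolic and thrombotic events, arterial",narrow,20000081,Myocardial infarction
20000082,"Embolic and thrombotic events, arterial",narrow,20000081,Cerebrovascular accident
20000082,"Embolic and thrombotic events, arterial",narrow,20000081,Arterial thrombosis
20000084,"Embolic and thrombotic events, venous",narrow,20000081,Deep vein thrombosis
20000084,"Embolic and thrombotic events, venous",narrow,20000081,Pulmonary embolism
20000084,"Embolic and thrombotic events, venous",narrow,20000081,Venous thrombosis
20000083,"Embolic and thrombotic events, vessel type unspecified and mixed",narrow,20000081,Thrombosis
20000083,"Embolic and thrombotic events, vessel type unspecified and mixed",narrow,20000081,Embolism venous and arterial mixed
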