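code,group
Office,Ambulatory
UrgentCare,Ambulatory
AmbulatorySurgery,Ambulatory
InpatientHospital,Hospital
OutpatientHospital,Hospital
EmergencyRoom,Hospital
IndependentLab,Lab
Home,Home
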