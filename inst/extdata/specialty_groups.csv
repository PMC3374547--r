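code,group
GeneralPractice,PrimaryCare
Internal,PrimaryCare
Pediatrics,PrimaryCare
ObGyn,PrimaryCare
Cardiology,Specialist
Oncology,Specialist
Psychiatry,Specialist
Orthopedics,Surgical
Surgery,Surgical
Radiology,Diagnostic
Laboratory,Diagnostic
Emergency,Acute
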