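code,group
250,Diabetes
401,Hypertension
402,Hypertension
272,LipidMetabolism
414,IschemicHeart
428,HeartFailure
427,Arrhythmia
486,Pneumonia
491,COPD
493,Asthma
530,Gastrointestinal
571,LiverDisease
585,RenalFailure
599,UrinaryTract
715,Arthropathy
724,BackProblems
780,GeneralSymptoms
786,RespiratorySymptoms
042,InfectiousDisease
140,Neoplasm
196,Neoplasm
290,MentalHealth
296,MentalHealth
635,PregnancyRelated
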