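code,group
99203,EvaluationManagement
99213,EvaluationManagement
99214,EvaluationManagement
99232,EvaluationManagement
99284,EvaluationManagement
99285,EvaluationManagement
12001,Surgery
36415,Surgery
45378,Surgery
47562,Surgery
27447,Surgery
59400,Surgery
70450,Radiology
71020,Radiology
72148,Radiology
76700,Radiology
80053,PathologyLab
80061,PathologyLab
85025,PathologyLab
87086,PathologyLab
90471,Medicine
93000,Medicine
94010,Medicine
96372,Medicine
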