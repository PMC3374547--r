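code,weight
250,1
428,1
491,1
493,1
571,3
585,2
140,2
196,6
290,1
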