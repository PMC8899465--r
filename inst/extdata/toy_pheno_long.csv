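subject,time,value
s1,1,1.1
s1,2,1.4
s1,3,1.9
s2,1,0.8
s2,2,1.2
s2,3,1.5
s3,1,1.0
s3,2,1.1
s3,3,1.3
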