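scale,range,information
WNSS-21,full,59.36
WNSS-21,range33,43.42
WNSS-8,full,39.89
WNSS-8,range33,31.72
NSS-SF,full,22.93
NSS-SF,range33,18.75
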