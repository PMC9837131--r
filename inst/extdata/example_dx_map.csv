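source,target
331.0,290.11
290.1,290.1
428.0,428.1
272.4,272.1
401.9,401.1
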