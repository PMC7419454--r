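{"command":"masks","flags":{"out":true},"package_version":"0.1.0","r_version":"R version 4.3.3 (2024-02-29)"}
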