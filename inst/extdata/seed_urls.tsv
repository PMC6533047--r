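url	label
https://www.aa.example.org/	AA
https://www.aa.example.org/find-a-meeting	AA
https://www.aa.example.org/twelve-steps	AA
https://intergroup.aa.example.org/meetings	AA
https://www.na.example.org/	NA
https://www.na.example.org/meetingsearch	NA
https://www.na.example.org/information	NA
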