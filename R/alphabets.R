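# Sequence alphabets used package-wide.
.NT <- c("A", "C", "G", "T")
.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.NT_OK <- c(.NT, "N")
.AA_OK <- c(.AA, "X")
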