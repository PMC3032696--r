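.datatable.aware <- TRUE

utils::globalVariables(c("kmer", "pos", "ref", "q", "mm", "strand", "off",
                         "i", "j", "nr", "pos1", "pos2", "mm1", "mm2",
                         "strand1", "strand2", "fwd", "rev", "ins", "s",
                         ".I", ".N", ".SD"))
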