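["Illumina Genome Analyzer II", "Illumina HiSeq 1500", "Illumina HiSeq 2000", "Illumina HiSeq 2500", "Illumina HiSeq 3000", "Illumina HiSeq 4000", "Illumina HiSeq X Ten", "Illumina MiSeq", "Illumina NovaSeq 6000", "NextSeq 500", "NextSeq 550", "NextSeq 2000", "unknown"]
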