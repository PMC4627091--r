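>synthetic_aptamer_87nt synthetic reference (fixed-seed draw, not a natural sequence)
CCGUGGGCUCUUCGGCGAGUGACGACAUCCUGCGCCUGUCAAACCUAAGCGUGCCACUGGCGACAAUAUCCCAGUCUCACUAGUCCG
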