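# Illustrative mutation list for a triosephosphate-isomerase-like chain.
# One compact mutation per line; substitutions (V51R), deletions (F508del)
# and insertions (508insG) are accepted.  This list is an example only: it
# is NOT the defective-sequence mutation set of any published contest.
V51R
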