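>precursor_inverted_locus flanking BAP31, inverted-orientation strains
MEPETLKNIFFQEASQDHLKDEAILFETSIGMPEISSEDLANSNNPINDSTGGDNADTMYCIIV
>precursor_reference_locus between STE3 and CAF1, reference-orientation strains
MIPEIEVSQIQVDQVHINVEREEPGENETYGSSSGCIIT
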