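>syn_hd1 synthetic Antp-type homeodomain reference (canonical consensus)
RKRGRQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEN
>syn_hd2 synthetic variant, Ubx-like C-terminal changes
RRRGRQTYTRYQTLELEKEFHTNHYLTRRRRIEMAHALCLTERQIKIWFQNRRMKLKKEI
>syn_hd3 synthetic variant, Scr-like N-terminal changes
TKRQRTSYTRYQTLELEKEFHFNRYLTRRRRIEIAHALCLTERQIKIWFQNRRMKWKKEH
>syn_hd4 synthetic variant, Dfd-like
PKRQRTAYTRHQILELEKEFHYNRYLTRRRRIEIAHTLVLSERQIKIWFQNRRMKWKKDN
>syn_hd5 synthetic variant, lab-like
NNSGRTNFTNKQLTELEKEFHFNRYLTRARRIEIANTLQLNETQVKIWFQNRRMKQKKRV
>syn_hd6 synthetic variant, pb-like
PKRQRTAYTSAQLVELEKEFHFNRYLCRPRRIEMAALLELTERQIKIWFQNRRMKYKKDQ
>syn_hd7 synthetic variant, abd-A-like
RRRGRQTYTRFQTLELEKEFHFNHYLTRRRRIEIAHALCLTERQIKIWFQNRRMKLKKEL
>syn_hd8 synthetic variant, Abd-B-like
VRKKRKPYSKFQTLELEKEFLFNAYVSKQKRWELARNLQLTERQVKIWFQNRRMKNKKNS
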