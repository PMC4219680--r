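# Default cofactor list: ubiquitous carrier species excluded from
# reaction-graph edge formation. One name per line; map names onto a
# model's id convention with an alias table (see cofactor_aliases_ecoli.tsv).
H
AMP
ADP
ATP
CoA
NAD
NADH
NADP
NADPH
phosphate
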