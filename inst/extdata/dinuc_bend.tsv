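# Dinucleotide bendability used as the DNA-bending (TBP complex
# stabilisation) term: negated bending-stiffness scale, arbitrary units.
# provenance: dinucleotide bending stiffness (Sivolob & Khrapunov-type
#   scale: AT/TA 20, AA/TT 35, CG/GC 85, CC/GG 130, all others 60), negated
#   so that larger values mean more bendable steps.
# property: bend
# orientation: higher = more bendable (TA steps bend most, GC-rich least)
# symmetric: TRUE
dinuc	value
aa	-35
ac	-60
ag	-60
at	-20
ca	-60
cc	-130
cg	-85
ct	-60
ga	-60
gc	-85
gg	-130
gt	-60
ta	-20
tc	-60
tg	-60
tt	-35
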