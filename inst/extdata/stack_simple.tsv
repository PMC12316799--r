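# Simplified additive nearest-neighbour stacking table (kcal/mol).
# dG of stacking pair2 on top of pair1; NOT Turner-2004-calibrated.
# bulge1 = 3.8
# internal11 = 1.2
pair1	pair2	dG
AU	AU	-1.2
UA	AU	-1.2
GC	AU	-2.2
CG	AU	-2.2
GU	AU	-1
UG	AU	-1
AU	UA	-1.2
UA	UA	-1.2
GC	UA	-2.2
CG	UA	-2.2
GU	UA	-1
UG	UA	-1
AU	GC	-2.2
UA	GC	-2.2
GC	GC	-3.2
CG	GC	-3.2
GU	GC	-2
UG	GC	-2
AU	CG	-2.2
UA	CG	-2.2
GC	CG	-3.2
CG	CG	-3.2
GU	CG	-2
UG	CG	-2
AU	GU	-1
UA	GU	-1
GC	GU	-2
CG	GU	-2
GU	GU	-0.8
UG	GU	-0.8
AU	UG	-1
UA	UG	-1
GC	UG	-2
CG	UG	-2
GU	UG	-0.8
UG	UG	-0.8
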