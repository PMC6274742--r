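accession	category
P30427	extracellular matrix
P69897	extracellular matrix
Q6P9T8	extracellular matrix
P05197	extracellular matrix
P61980	extracellular matrix
P61751	extracellular matrix
P62271	extracellular matrix
P45592	extracellular matrix
P49744	extracellular matrix
P02466	extracellular matrix
Q8CJD3	extracellular matrix
P51886	extracellular matrix
Q9EQP5	extracellular matrix
P47853	extracellular matrix
Q01129	extracellular matrix
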