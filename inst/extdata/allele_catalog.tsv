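# Milk protein allele catalog: named protein variants of the six bovine
# milk protein genes and their defining DNA site-alleles (ARS-UCD1.2-style
# coordinates; one row per allele x defining site).
# Alleles are forward-strand (VCF orientation). CSN2 lies on the reverse
# strand, so its published transcript-orientation alleles (rs43703011 A>C,
# rs715383373 T>C) appear here as their complements (T>G and A>G).
# The position of the LGB p.Asn88 synonymous site (rs110641366, part of the
# B1 definition) is not published; the coordinate below is the third base
# of mature codon 88 in the bundled synthetic LGB transcript model.
# status: reference = the gene's reference allele; known = previously
# described; novel = newly annotated.
gene	allele_name	chrom	pos	ref	alt	required_allele	status
CSN1S1	B	6	85427427	A	G	A	reference
CSN1S1	C	6	85427427	A	G	G	known
CSN2	A1	6	85450908	A	G	A	reference
CSN2	A1	6	85451298	T	G	T	reference
CSN2	A2	6	85450908	A	G	A	known
CSN2	A2	6	85451298	T	G	G	known
CSN2	L	6	85450908	A	G	G	known
CSN2	L	6	85451298	T	G	T	known
CSN1S2	A	6	85533780	C	T	C	reference
CSN1S2	B	6	85533780	C	T	T	known
CSN3	B	6	85656526	C	T	C	reference
CSN3	B	6	85656736	T	C	T	reference
CSN3	B	6	85656772	C	A	C	reference
CSN3	A	6	85656526	C	T	C	known
CSN3	A	6	85656736	T	C	C	known
CSN3	A	6	85656772	C	A	A	known
CSN3	K	6	85656526	C	T	T	novel
CSN3	K	6	85656736	T	C	T	novel
CSN3	K	6	85656772	C	A	C	novel
LALBA	B	5	31184282	C	T	C	reference
LALBA	B	5	31184283	G	A	G	reference
LALBA	B	5	31184696	A	G	A	reference
LALBA	A	5	31184282	C	T	C	known
LALBA	A	5	31184283	G	A	A	known
LALBA	A	5	31184696	A	G	A	known
LALBA	E	5	31184282	C	T	C	known
LALBA	E	5	31184283	G	A	G	known
LALBA	E	5	31184696	A	G	G	known
LALBA	F	5	31184282	C	T	T	novel
LALBA	F	5	31184283	G	A	G	novel
LALBA	F	5	31184696	A	G	A	novel
LGB	B	11	103257970	T	C	T	reference
LGB	B	11	103257980	A	AA	A	reference
LGB	B	11	103259232	C	T	C	reference
LGB	B1	11	103257970	T	C	C	novel
LGB	B1	11	103257980	A	AA	A	novel
LGB	B1	11	103259232	C	T	T	novel
LGB	K	11	103257970	T	C	T	novel
LGB	K	11	103257980	A	AA	AA	novel
LGB	K	11	103259232	C	T	C	novel
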