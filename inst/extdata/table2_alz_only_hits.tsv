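gene	kegg_sets	deg_cases	direction	ign_cases	in_ad_pathway
ARPC1A	Ecol	HC,PC,SFG	Down		no
TUBA1B	Ecol	HC,PC,SFG,MTG	Down	AG,EC,HC,MTG,PC,SFG	no
TUBA1C	Ecol	HC,PC,MTG	Down	AG,HC,MTG,PC,SFG	no
TUBB	Ecol	HC,PC,SFG	Down	AG,EC,HC,MTG,PC,SFG	no
TUBB3	Ecol	PC,SFG,MTG	Down	AG,EC,MTG	no
ACYP2	Pym	HC,PC	Down		no
GLO1	Pym	HC,PC,MTG	Down		no
LDHB	Pym	HC,PC	Down		no
DLD	Pym,TCA	HC,PC,SFG	Down	HC,PC	no
MDH2	Pym,TCA	HC,SFG	Down	EC	no
PDHA1	Pym,TCA	HC,SFG	Down		no
PDHB	Pym,TCA	PC,SFG	Down	HC,SFG	no
FH	TCA	PC,SFG,MTG	Down		no
IDH3G	TCA	EC,HC,SFG	Down		no
SDHA	TCA,Oxp	HC,PC	Down	AG	yes
ATP6V1E1	Vch,Oxp	HC,PC,SFG,MTG	Down	EC,HC,MTG	no
ATP6V1H	Vch,Oxp	HC,PC	Down	EC,HC,MTG	no
ATP5J2	Oxp	PC,SFG,EC,MTG	Down		no
ATP5L	Oxp	PC,SFG,MTG	Down		no
ATP5A1	Oxp	HC,PC	Down	EC,HC,SFG	yes
ATP5B	Oxp	HC,PC,SFG	Down	EC,HC,MTG,SFG	yes
ATP5C1	Oxp	PC,SFG,MTG	Down	EC,HC,MTG,SFG	yes
ATP5G3	Oxp	HC,PC,SFG	Down		yes
ATP5O	Oxp	HC,PC,SFG	Down	EC	yes
COX4I1	Oxp	HC,PC	Down		yes
COX5B	Oxp	HC,PC	Down		yes
COX6B1	Oxp	HC,PC,MTG	Down		yes
COX6C	Oxp	HC,PC	Down		yes
NDUFA2	Oxp	PC,SFG	Down		yes
NDUFA8	Oxp	HC,SFG,MTG	Down		yes
NDUFA9	Oxp	HC,PC,SFG	Down	HC	yes
NDUFAB1	Oxp	HC,PC,SFG,MTG	Down		yes
NDUFB10	Oxp	HC,PC	Down		yes
NDUFC2	Oxp	PC,SFG	Down		yes
NDUFS3	Oxp	HC,PC,SFG	Down	PC	yes
NDUFS5	Oxp	HC,PC,SFG,MTG	Down		yes
NDUFV2	Oxp	HC,PC,SFG	Down	HC	yes
UQCRC2	Oxp	HC,PC,SFG	Down	AG	yes
UQCR10	Oxp	HC,SFG	Down		yes
UQCRH	Oxp	HC,SFG,MTG	Down	AG,HC,PC	yes
POMP	PSM	HC,PC	Down	EC,HC,PC	no
PSMA1	PSM	HC,PC,SFG,MTG	Down	AG,EC,HC,MTG,PC	no
PSMB1	PSM	HC,PC	Down	AG,MTG	no
PSMB2	PSM	HC,SFG	Down	HC	no
PSMB3	PSM	HC,PC,SFG	Down	HC	no
PSMB4	PSM	HC,PC	Down		no
PSMB5	PSM	PC,SFG	Down	HC,MTG	no
PSMB6	PSM	HC,PC	Down		no
PSMC1	PSM	HC,PC,SFG	Down	AG,HC	no
PSMC2	PSM	HC,PC,SFG	Down	AG,EC,HC,MTG,PC	no
PSMC5	PSM	HC,PC,MTG	Down	AG,EC,MTG,SFG	no
PSMD4	PSM	HC,PC	Down	AG,EC,HC,MTG,PC,SFG	no
PSMD8	PSM	PC,SFG	Down	HC,MTG,PC	no
PSMD12	PSM	HC,PC	Down	EC,HC	no
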