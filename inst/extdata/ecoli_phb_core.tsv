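# model: ecoli_phb_core
# version: 1.0 (P/O NADH 2.5, quinol 1.5, maintenance 0)
# metabolites: 61
# reactions: 66
# objective_candidates: EX_phb_e
[metabolites]
id	name	formula	compartment
g6p_c	D-glucose 6-phosphate	C6H11O9P	c
f6p_c	D-fructose 6-phosphate	C6H11O9P	c
fdp_c	D-fructose 1,6-bisphosphate	C6H10O12P2	c
dhap_c	dihydroxyacetone phosphate	C3H5O6P	c
g3p_c	glyceraldehyde 3-phosphate	C3H5O6P	c
13dpg_c	3-phospho-D-glyceroyl phosphate	C3H4O10P2	c
3pg_c	3-phospho-D-glycerate	C3H4O7P	c
2pg_c	2-phospho-D-glycerate	C3H4O7P	c
pep_c	phosphoenolpyruvate	C3H2O6P	c
pyr_c	pyruvate	C3H3O3	c
6pgl_c	6-phospho-D-glucono-1,5-lactone	C6H9O9P	c
6pgc_c	6-phospho-D-gluconate	C6H10O10P	c
ru5p__D_c	D-ribulose 5-phosphate	C5H9O8P	c
r5p_c	D-ribose 5-phosphate	C5H9O8P	c
xu5p__D_c	D-xylulose 5-phosphate	C5H9O8P	c
s7p_c	sedoheptulose 7-phosphate	C7H13O10P	c
e4p_c	D-erythrose 4-phosphate	C4H7O7P	c
xyl__D_c	D-xylose	C5H10O5	c
xylu__D_c	D-xylulose	C5H10O5	c
glyc_c	glycerol	C3H8O3	c
glyc3p_c	sn-glycerol 3-phosphate	C3H7O6P	c
dha_c	dihydroxyacetone	C3H6O3	c
accoa_c	acetyl-CoA	C23H34N7O17P3S	c
coa_c	coenzyme A	C21H32N7O16P3S	c
actp_c	acetyl phosphate	C2H3O5P	c
ac_c	acetate	C2H3O2	c
aacoa_c	acetoacetyl-CoA	C25H36N7O18P3S	c
3hbcoa_c	(R)-3-hydroxybutyryl-CoA	C25H38N7O18P3S	c
phb_c	P3HB monomer unit	C4H6O2	c
cit_c	citrate	C6H5O7	c
icit_c	isocitrate	C6H5O7	c
akg_c	2-oxoglutarate	C5H4O5	c
succoa_c	succinyl-CoA	C25H35N7O19P3S	c
succ_c	succinate	C4H4O4	c
fum_c	fumarate	C4H2O4	c
mal__L_c	L-malate	C4H4O5	c
oaa_c	oxaloacetate	C4H2O5	c
nad_c	NAD+	C21H26N7O14P2	c
nadh_c	NADH	C21H27N7O14P2	c
nadp_c	NADP+	C21H25N7O17P3	c
nadph_c	NADPH	C21H26N7O17P3	c
atp_c	ATP	C10H12N5O13P3	c
adp_c	ADP	C10H12N5O10P2	c
amp_c	AMP	C10H12N5O7P	c
pi_c	phosphate	HO4P	c
q8_c	ubiquinone-8	C49H74O4	c
q8h2_c	ubiquinol-8	C49H76O4	c
h2o_c	water	H2O	c
h_c	proton	H	c
co2_c	carbon dioxide	CO2	c
o2_c	oxygen	O2	c
glc__D_e	D-glucose	C6H12O6	e
xyl__D_e	D-xylose	C5H10O5	e
glyc_e	glycerol	C3H8O3	e
o2_e	oxygen	O2	e
co2_e	carbon dioxide	CO2	e
h2o_e	water	H2O	e
pi_e	phosphate	HO4P	e
h_e	proton	H	e
ac_e	acetate	C2H3O2	e
phb_e	P3HB monomer unit	C4H6O2	e
[reactions]
id	name	equation	lower_bound	upper_bound	subsystem
EX_glc__D_e	glucose exchange	glc__D_e <-> 	-1000	1000	exchange
EX_xyl__D_e	xylose exchange	xyl__D_e <-> 	-1000	1000	exchange
EX_glyc_e	glycerol exchange	glyc_e <-> 	-1000	1000	exchange
EX_o2_e	oxygen exchange	o2_e <-> 	-1000	1000	exchange
EX_co2_e	carbon dioxide exchange	co2_e -> 	0	1000	exchange
EX_h2o_e	water exchange	h2o_e <-> 	-1000	1000	exchange
EX_pi_e	phosphate exchange	pi_e <-> 	-1000	1000	exchange
EX_h_e	proton exchange	h_e <-> 	-1000	1000	exchange
EX_ac_e	acetate exchange	ac_e -> 	0	1000	exchange
EX_phb_e	P3HB monomer drain	phb_e -> 	0	1000	exchange
GLCpts	glucose PTS	glc__D_e + pep_c -> g6p_c + pyr_c	0	1000	transport
XYLt2	xylose proton symport	h_e + xyl__D_e -> h_c + xyl__D_c	0	1000	transport
GLYCt	glycerol facilitated diffusion	glyc_e <-> glyc_c	-1000	1000	transport
O2t	oxygen diffusion	o2_e <-> o2_c	-1000	1000	transport
CO2t	carbon dioxide diffusion	co2_c <-> co2_e	-1000	1000	transport
H2Ot	water diffusion	h2o_c <-> h2o_e	-1000	1000	transport
PIt	phosphate transport	pi_e <-> pi_c	-1000	1000	transport
Ht	proton diffusion	h_e <-> h_c	-1000	1000	transport
ACt	acetate export	ac_c <-> ac_e	-1000	1000	transport
PHBt	P3HB monomer export	phb_c -> phb_e	0	1000	transport
PGI	glucose-6-phosphate isomerase	g6p_c <-> f6p_c	-1000	1000	glycolysis
PFK	phosphofructokinase	atp_c + f6p_c -> adp_c + fdp_c + h_c	0	1000	glycolysis
FBP	fructose-1,6-bisphosphatase	fdp_c + h2o_c -> f6p_c + pi_c	0	1000	glycolysis
FBA	fructose-bisphosphate aldolase	fdp_c <-> dhap_c + g3p_c	-1000	1000	glycolysis
TPI	triose-phosphate isomerase	dhap_c <-> g3p_c	-1000	1000	glycolysis
GAPD	glyceraldehyde-3-phosphate dehydrogenase	g3p_c + nad_c + pi_c <-> 13dpg_c + h_c + nadh_c	-1000	1000	glycolysis
PGK	phosphoglycerate kinase	13dpg_c + adp_c <-> 3pg_c + atp_c	-1000	1000	glycolysis
PGM	phosphoglycerate mutase	3pg_c <-> 2pg_c	-1000	1000	glycolysis
ENO	enolase	2pg_c <-> h2o_c + pep_c	-1000	1000	glycolysis
PYK	pyruvate kinase	adp_c + h_c + pep_c -> atp_c + pyr_c	0	1000	glycolysis
PPS	phosphoenolpyruvate synthase	atp_c + h2o_c + pyr_c -> amp_c + 2 h_c + pep_c + pi_c	0	1000	glycolysis
ADK1	adenylate kinase	amp_c + atp_c <-> 2 adp_c	-1000	1000	energy
G6PDH2	glucose-6-phosphate dehydrogenase	g6p_c + nadp_c -> 6pgl_c + h_c + nadph_c	0	1000	PPP
PGL	6-phosphogluconolactonase	6pgl_c + h2o_c -> 6pgc_c + h_c	0	1000	PPP
GND	6-phosphogluconate dehydrogenase	6pgc_c + nadp_c -> co2_c + nadph_c + ru5p__D_c	0	1000	PPP
RPI	ribose-5-phosphate isomerase	r5p_c <-> ru5p__D_c	-1000	1000	PPP
RPE	ribulose-5-phosphate 3-epimerase	ru5p__D_c <-> xu5p__D_c	-1000	1000	PPP
TKT1	transketolase 1	r5p_c + xu5p__D_c <-> g3p_c + s7p_c	-1000	1000	PPP
TKT2	transketolase 2	e4p_c + xu5p__D_c <-> f6p_c + g3p_c	-1000	1000	PPP
TALA	transaldolase	g3p_c + s7p_c <-> e4p_c + f6p_c	-1000	1000	PPP
XYLI1	xylose isomerase	xyl__D_c <-> xylu__D_c	-1000	1000	xylose
XYLK	xylulokinase	atp_c + xylu__D_c -> adp_c + h_c + xu5p__D_c	0	1000	xylose
GLYK	glycerol kinase	atp_c + glyc_c -> adp_c + glyc3p_c + h_c	0	1000	glycerol
G3PD5	glycerol-3-phosphate dehydrogenase (quinone)	glyc3p_c + q8_c -> dhap_c + q8h2_c	0	1000	glycerol
GLYCDx	glycerol dehydrogenase	glyc_c + nad_c <-> dha_c + h_c + nadh_c	-1000	1000	glycerol
DHAPT	dihydroxyacetone kinase (PEP)	dha_c + pep_c -> dhap_c + pyr_c	0	1000	glycerol
F6PA	fructose-6-phosphate aldolase	f6p_c <-> dha_c + g3p_c	-1000	1000	glycerol
PDH	pyruvate dehydrogenase	coa_c + nad_c + pyr_c -> accoa_c + co2_c + nadh_c	0	1000	pyruvate
PTAr	phosphotransacetylase	accoa_c + pi_c <-> actp_c + coa_c	-1000	1000	acetate
ACKr	acetate kinase	ac_c + atp_c <-> actp_c + adp_c	-1000	1000	acetate
PHAA	acetyl-CoA acetyltransferase (phaA)	2 accoa_c <-> aacoa_c + coa_c	-1000	1000	PHB
PHAB	acetoacetyl-CoA reductase (phaB)	aacoa_c + h_c + nadph_c -> 3hbcoa_c + nadp_c	0	1000	PHB
PHAC	PHA synthase monomer drain (phaC)	3hbcoa_c -> coa_c + phb_c	0	1000	PHB
CS	citrate synthase	accoa_c + h2o_c + oaa_c -> cit_c + coa_c + h_c	0	1000	TCA
ACONT	aconitase	cit_c <-> icit_c	-1000	1000	TCA
ICDHy	isocitrate dehydrogenase (NADP)	icit_c + nadp_c -> akg_c + co2_c + nadph_c	0	1000	TCA
AKGDH	2-oxoglutarate dehydrogenase	akg_c + coa_c + nad_c -> co2_c + nadh_c + succoa_c	0	1000	TCA
SUCOAS	succinyl-CoA synthetase	adp_c + pi_c + succoa_c <-> atp_c + coa_c + succ_c	-1000	1000	TCA
SUCDi	succinate dehydrogenase	q8_c + succ_c -> fum_c + q8h2_c	0	1000	TCA
FUM	fumarase	fum_c + h2o_c <-> mal__L_c	-1000	1000	TCA
MDH	malate dehydrogenase	mal__L_c + nad_c <-> h_c + nadh_c + oaa_c	-1000	1000	TCA
PPC	PEP carboxylase	co2_c + h2o_c + pep_c -> h_c + oaa_c + pi_c	0	1000	anaplerosis
NADHOR	NADH oxidation lumped to ATP synthesis	2.5 adp_c + 3.5 h_c + nadh_c + 0.5 o2_c + 2.5 pi_c -> 2.5 atp_c + 3.5 h2o_c + nad_c	0	1000	oxphos
QUINOR	ubiquinol oxidation lumped to ATP synthesis	1.5 adp_c + 1.5 h_c + 0.5 o2_c + 1.5 pi_c + q8h2_c -> 1.5 atp_c + 2.5 h2o_c + q8_c	0	1000	oxphos
THD	transhydrogenase (uncoupled lump)	nadh_c + nadp_c <-> nad_c + nadph_c	-1000	1000	energy
ATPM	ATP maintenance drain	atp_c + h2o_c -> adp_c + h_c + pi_c	0	1000	energy
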