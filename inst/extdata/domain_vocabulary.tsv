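label	description
ART	ADP-ribosyl transferase domain; binds NAD+ and transfers ADP-ribose onto substrates
HD	Helical domain: the autoinhibitory regulatory helical subdomain of PARP1, conserved in PARP2/3/4; with ART it forms the CAT domain
HE	Helical extension: structurally distinct all-helical appendage to the ART in PARP6/8/16; does not occlude the NAD+ site
CAT	Catalytic domain composed of HD and ART
ZnF	Zinc finger (generic)
CCHC	CCHC-type zinc finger (PARP1 ZnF1/ZnF2 class)
C4	C4-type zinc finger as in the third ZnF of PARP1
C4*	Second, structurally distinct C4-type zinc finger found in PARP6 and PARP8
CCCH	CCCH-type zinc finger as in the MZAP/NZAP arrangements
CHCC	CHCC-type zinc finger integrated in the tankyrase ART
WGR	Domain named after conserved Trp-Gly-Arg residues; DNA-damage detection module
BRCT	BRCA1 C-terminus domain; protein/DNA/PAR interaction module
WWE	Small beta-grasp domain named after conserved Trp-Trp-Glu; often a PAR reader
MZAP	Middle domain of ZAP: compact CCCH ZnF + two WWE arrangement in PARP7/12/13
NZAP	N-terminal domain of ZAP: four CCCH ZnFs with helices and a beta-sheet; RNA recognition
MVPID	Major-vault-protein interacting domain: all-helical C-terminal domain of PARP4
ITIHL	Inter-alpha-trypsin heavy-chain-like region (VIT + vWA + further elements) of PARP4
VIT	Vault protein inter-alpha-trypsin domain
vWA	von Willebrand factor type A domain
KH	K-homology domain (type I); sequence-specific ssRNA/ssDNA binding
RWD	Domain related to the ubiquitin-conjugating (UBC/E2) core, typically without the catalytic cysteine
Macro	Macrodomain; ADP-ribose binding module
RRM	RNA recognition motif
SAM	Sterile alpha motif; mediates head-to-tail polymerisation in tankyrases
ARC	Ankyrin repeat cluster; tankyrase substrate recruitment platform
UIM	Ubiquitin-interacting motif
TM	Transmembrane helix
HPS	His-, Pro-, Ser-rich disordered region of TNKS1 (not a structured domain)
unassigned	Structured element or connector without a homology label
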