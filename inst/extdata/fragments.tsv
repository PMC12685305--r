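id	smiles	attachments	class
FRAG001	c1ccccc1	1,2,3,4,5,6	aromatic
FRAG002	c1ccncc1	1,2,3,5,6	aromatic
FRAG003	c1ccncn1	1,2,3,5	aromatic
FRAG004	c1ccnnc1	1,2,3,6	aromatic
FRAG005	c1cc[nH]c1	1,2,3,4,5	aromatic
FRAG006	c1ccoc1	1,2,3,5	aromatic
FRAG007	c1ccsc1	1,2,3,5	aromatic
FRAG008	c1cnc[nH]1	1,2,4,5	aromatic
FRAG009	c1cn[nH]c1	1,2,4,5	aromatic
FRAG010	c1cnco1	1,2,4	aromatic
FRAG011	c1cncs1	1,2,4	aromatic
FRAG012	c1ccc2ccccc2c1	1,2,3,5,6,7,8,10	aromatic
FRAG013	c1ccc2[nH]ccc2c1	1,2,3,5,6,7,9	aromatic
FRAG014	c1ccc2occc2c1	1,2,3,6,7,9	aromatic
FRAG015	c1ccc2sccc2c1	1,2,3,6,7,9	aromatic
FRAG016	c1ccc2ncccc2c1	1,2,3,6,7,8,10	aromatic
FRAG017	c1ccccc1C	1,2,3,4,5,7	aromatic
FRAG018	c1ccccc1F	1,2,3,4,5	aromatic
FRAG019	c1ccccc1Cl	1,2,3,4,5	aromatic
FRAG020	c1ccccc1O	1,2,3,4,5,7	aromatic
FRAG021	c1ccccc1N	1,2,3,4,5,7	aromatic
FRAG022	c1ccccc1OC	1,2,3,4,5,8	aromatic
FRAG023	c1ccccc1C#N	1,2,3,4,5	aromatic
FRAG024	c1ccccc1C(F)(F)F	1,2,3,4,5	aromatic
FRAG025	c1ccccc1CC	1,2,3,4,5,7,8	aromatic
FRAG026	c1ccccc1C=O	1,2,3,4,5,7	aromatic
FRAG027	c1ccccc1C(=O)N	1,2,3,4,5,9	aromatic
FRAG028	c1ccccc1S(=O)(=O)N	1,2,3,4,5,10	aromatic
FRAG029	c1ccncc1C	1,2,3,5,7	aromatic
FRAG030	c1ccncc1F	1,2,3,5	aromatic
FRAG031	c1ccncc1Cl	1,2,3,5	aromatic
FRAG032	c1ccncc1O	1,2,3,5,7	aromatic
FRAG033	c1ccncc1N	1,2,3,5,7	aromatic
FRAG034	c1ccncc1OC	1,2,3,5,8	aromatic
FRAG035	c1ccncc1C#N	1,2,3,5	aromatic
FRAG036	c1ccncc1C(F)(F)F	1,2,3,5	aromatic
FRAG037	c1ccncc1CC	1,2,3,5,7,8	aromatic
FRAG038	c1ccncc1C=O	1,2,3,5,7	aromatic
FRAG039	c1ccncc1C(=O)N	1,2,3,5,9	aromatic
FRAG040	c1ccncc1S(=O)(=O)N	1,2,3,5,10	aromatic
FRAG041	c1ccsc1C	1,2,3,6	aromatic
FRAG042	c1ccsc1F	1,2,3	aromatic
FRAG043	c1ccsc1Cl	1,2,3	aromatic
FRAG044	c1ccsc1O	1,2,3,6	aromatic
FRAG045	c1ccsc1N	1,2,3,6	aromatic
FRAG046	c1ccsc1OC	1,2,3,7	aromatic
FRAG047	c1ccsc1C#N	1,2,3	aromatic
FRAG048	c1ccsc1C(F)(F)F	1,2,3	aromatic
FRAG049	c1ccsc1CC	1,2,3,6,7	aromatic
FRAG050	c1ccsc1C=O	1,2,3,6	aromatic
FRAG051	c1ccsc1C(=O)N	1,2,3,8	aromatic
FRAG052	c1ccsc1S(=O)(=O)N	1,2,3,9	aromatic
FRAG053	c1ccoc1C	1,2,3,6	aromatic
FRAG054	c1ccoc1F	1,2,3	aromatic
FRAG055	c1ccoc1Cl	1,2,3	aromatic
FRAG056	c1ccoc1O	1,2,3,6	aromatic
FRAG057	c1ccoc1N	1,2,3,6	aromatic
FRAG058	c1ccoc1OC	1,2,3,7	aromatic
FRAG059	c1ccoc1C#N	1,2,3	aromatic
FRAG060	c1ccoc1C(F)(F)F	1,2,3	aromatic
FRAG061	c1ccoc1CC	1,2,3,6,7	aromatic
FRAG062	c1ccoc1C=O	1,2,3,6	aromatic
FRAG063	c1ccoc1C(=O)N	1,2,3,8	aromatic
FRAG064	c1ccoc1S(=O)(=O)N	1,2,3,9	aromatic
FRAG065	c1cc[nH]c1C	1,2,3,4,6	aromatic
FRAG066	c1cc[nH]c1F	1,2,3,4	aromatic
FRAG067	c1cc[nH]c1Cl	1,2,3,4	aromatic
FRAG068	c1cc[nH]c1O	1,2,3,4,6	aromatic
FRAG069	c1cc[nH]c1N	1,2,3,4,6	aromatic
FRAG070	c1cc[nH]c1OC	1,2,3,4,7	aromatic
FRAG071	c1cc[nH]c1C#N	1,2,3,4	aromatic
FRAG072	c1cc[nH]c1C(F)(F)F	1,2,3,4	aromatic
FRAG073	c1cc[nH]c1CC	1,2,3,4,6,7	aromatic
FRAG074	c1cc[nH]c1C=O	1,2,3,4,6	aromatic
FRAG075	c1cc[nH]c1C(=O)N	1,2,3,4,8	aromatic
FRAG076	c1cc[nH]c1S(=O)(=O)N	1,2,3,4,9	aromatic
FRAG077	c1cc(C)ccc1C	1,2,4,5,6,8	aromatic
FRAG078	c1cc(C)ccc1O	1,2,4,5,6,8	aromatic
FRAG079	c1cc(F)ccc1C	1,2,5,6,8	aromatic
FRAG080	c1cc(F)ccc1O	1,2,5,6,8	aromatic
FRAG081	c1cc(Cl)ccc1C	1,2,5,6,8	aromatic
FRAG082	c1cc(Cl)ccc1O	1,2,5,6,8	aromatic
FRAG083	c1cc(O)ccc1O	1,2,4,5,6,8	aromatic
FRAG084	c1cc(N)ccc1C	1,2,4,5,6,8	aromatic
FRAG085	c1cc(N)ccc1O	1,2,4,5,6,8	aromatic
FRAG086	c1cc(OC)ccc1C	1,2,5,6,7,9	aromatic
FRAG087	c1cc(OC)ccc1O	1,2,5,6,7,9	aromatic
FRAG088	C1CC1	1,2,3	hydrophobe
FRAG089	C1CCC1	1,2,3,4	hydrophobe
FRAG090	C1CCCC1	1,2,3,4,5	hydrophobe
FRAG091	C1CCCCC1	1,2,3,4,5,6	hydrophobe
FRAG092	C1CCNCC1	1,2,3,4,5,6	hydrophobe
FRAG093	C1CCOCC1	1,2,3,5,6	hydrophobe
FRAG094	C1CNCCN1	1,2,3,4,5,6	hydrophobe
FRAG095	C1COCCN1	1,2,4,5,6	hydrophobe
FRAG096	C1CCSCC1	1,2,3,5,6	hydrophobe
FRAG097	C1CCOC1	1,2,3,5	hydrophobe
FRAG098	C1CCNC1	1,2,3,4,5	hydrophobe
FRAG099	C1CCCCCC1	1,2,3,4,5,6,7	hydrophobe
FRAG100	C1CCCCC1C	1,2,3,4,5,6,7	hydrophobe
FRAG101	C1CCCCC1O	1,2,3,4,5,6,7	hydrophobe
FRAG102	C1CCCCC1N	1,2,3,4,5,6,7	hydrophobe
FRAG103	C1CCCCC1CC	1,2,3,4,5,6,7,8	hydrophobe
FRAG104	C1CCCCC1C=O	1,2,3,4,5,6,7	hydrophobe
FRAG105	C1CCNCC1C	1,2,3,4,5,6,7	hydrophobe
FRAG106	C1CCNCC1O	1,2,3,4,5,6,7	hydrophobe
FRAG107	C1CCNCC1N	1,2,3,4,5,6,7	hydrophobe
FRAG108	C1CCNCC1CC	1,2,3,4,5,6,7,8	hydrophobe
FRAG109	C1CCNCC1C=O	1,2,3,4,5,6,7	hydrophobe
FRAG110	C1CCOCC1C	1,2,3,5,6,7	hydrophobe
FRAG111	C1CCOCC1O	1,2,3,5,6,7	hydrophobe
FRAG112	C1CCOCC1N	1,2,3,5,6,7	hydrophobe
FRAG113	C1CCOCC1CC	1,2,3,5,6,7,8	hydrophobe
FRAG114	C1CCOCC1C=O	1,2,3,5,6,7	hydrophobe
FRAG115	C1CNCCN1C	1,2,3,4,5,7	hydrophobe
FRAG116	C1CNCCN1O	1,2,3,4,5,7	hydrophobe
FRAG117	C1CNCCN1N	1,2,3,4,5,7	hydrophobe
FRAG118	C1CNCCN1CC	1,2,3,4,5,7,8	hydrophobe
FRAG119	C1CNCCN1C=O	1,2,3,4,5,7	hydrophobe
FRAG120	C1CCOC1C	1,2,3,5,6	hydrophobe
FRAG121	C1CCOC1O	1,2,3,5,6	hydrophobe
FRAG122	C1CCOC1N	1,2,3,5,6	hydrophobe
FRAG123	C1CCOC1CC	1,2,3,5,6,7	hydrophobe
FRAG124	C1CCOC1C=O	1,2,3,5,6	hydrophobe
FRAG125	C	1	linker
FRAG126	CC	1,2	linker
FRAG127	CCC	1,2,3	linker
FRAG128	CCCC	1,2,3,4	linker
FRAG129	C=C	1,2	linker
FRAG130	C#C	1,2	linker
FRAG131	O	1	linker
FRAG132	N	1	linker
FRAG133	S	1	linker
FRAG134	CO	1,2	linker
FRAG135	CN	1,2	linker
FRAG136	OC=O	1,2	linker
FRAG137	NC=O	1,2	linker
FRAG138	C(=O)C	1,3	linker
FRAG139	S(=O)(=O)C	1,4	linker
FRAG140	NC(=O)N	1,4	linker
FRAG141	COC	1,3	linker
FRAG142	CNC	1,2,3	linker
FRAG143	OCC	1,2,3	linker
FRAG144	NCC	1,2,3	linker
FRAG145	CC(C)C	1,2,3,4	linker
FRAG146	OCCO	1,2,3,4	linker
FRAG147	NCCN	1,2,3,4	linker
FRAG148	OCCN	1,2,3,4	linker
FRAG149	SCC	1,2,3	linker
FRAG150	CC=CC	1,2,3,4	linker
FRAG151	CC#CC	1,4	linker
FRAG152	NCCCN	1,2,3,4,5	linker
FRAG153	OCCCO	1,2,3,4,5	linker
FRAG154	C(=O)CC	1,3,4	linker
FRAG155	CS(=O)(=O)C	1,5	linker
FRAG156	ON	1,2	donor
FRAG157	NN	1,2	donor
FRAG158	NC(=O)C	1,4	donor
FRAG159	NC(C)C	1,2,3,4	donor
FRAG160	OC(C)C	1,2,3,4	donor
FRAG161	NC(=O)CC	1,4,5	donor
FRAG162	OCCC	1,2,3,4	donor
FRAG163	NCCC	1,2,3,4	donor
FRAG164	C=O	1	acceptor
FRAG165	C#N	1	acceptor
FRAG166	C(=O)OC	1,4	acceptor
FRAG167	S(=O)(=O)N	1,4	acceptor
FRAG168	OC(F)(F)F	1	acceptor
FRAG169	C(=O)N(C)C	1,4,5	acceptor
FRAG170	C(=O)NC	1,3,4	acceptor
FRAG171	OC(=O)C	1,4	acceptor
FRAG172	C(=O)OCC	1,4,5	acceptor
FRAG173	CCC(C)C	1,2,3,4,5	hydrophobe
FRAG174	F	1	hydrophobe
FRAG175	Cl	1	hydrophobe
FRAG176	Br	1	hydrophobe
FRAG177	I	1	hydrophobe
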