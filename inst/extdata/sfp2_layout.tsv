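well	substrate	is_water
A1	water	1
A2	C002	0
A3	C003	0
A4	C004	0
A5	C005	0
A6	C006	0
A7	C007	0
A8	C008	0
A9	C009	0
A10	C010	0
A11	C011	0
A12	C012	0
B1	C013	0
B2	C014	0
B3	C015	0
B4	C016	0
B5	C017	0
B6	C018	0
B7	C019	0
B8	C020	0
B9	C021	0
B10	C022	0
B11	C023	0
B12	C024	0
C1	C025	0
C2	C026	0
C3	C027	0
C4	C028	0
C5	C029	0
C6	C030	0
C7	C031	0
C8	C032	0
C9	C033	0
C10	C034	0
C11	C035	0
C12	C036	0
D1	C037	0
D2	C038	0
D3	C039	0
D4	C040	0
D5	C041	0
D6	C042	0
D7	C043	0
D8	C044	0
D9	C045	0
D10	C046	0
D11	C047	0
D12	C048	0
E1	C049	0
E2	C050	0
E3	C051	0
E4	C052	0
E5	C053	0
E6	C054	0
E7	C055	0
E8	C056	0
E9	C057	0
E10	C058	0
E11	C059	0
E12	C060	0
F1	C061	0
F2	C062	0
F3	C063	0
F4	C064	0
F5	C065	0
F6	C066	0
F7	C067	0
F8	C068	0
F9	C069	0
F10	C070	0
F11	C071	0
F12	C072	0
G1	C073	0
G2	C074	0
G3	C075	0
G4	C076	0
G5	C077	0
G6	C078	0
G7	C079	0
G8	C080	0
G9	C081	0
G10	C082	0
G11	C083	0
G12	C084	0
H1	C085	0
H2	C086	0
H3	C087	0
H4	C088	0
H5	C089	0
H6	C090	0
H7	C091	0
H8	C092	0
H9	C093	0
H10	C094	0
H11	C095	0
H12	C096	0
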