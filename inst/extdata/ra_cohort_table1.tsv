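sample_id	cohort	group	age	race	cell_type
ANWC01	ANW	control	74	Caucasian	buccal
ANWC02	ANW	control	56	Caucasian	buccal
ANWC03	ANW	control	39	Not specified	buccal
ANWC04	ANW	control	56	Caucasian	buccal
ANWC05	ANW	control	59	Caucasian	buccal
ANWC06	ANW	control	68	Caucasian	buccal
ANWC07	ANW	control	55	Caucasian	buccal
ANWC08	ANW	control	70	Caucasian	buccal
ANWC09	ANW	control	49	Caucasian	buccal
ANWC10	ANW	control	62	Caucasian	buccal
ANWC11	ANW	control	30	Caucasian	buccal
ANWC12	ANW	control	51	Caucasian	buccal
ANWC13	ANW	control	45	Caucasian	buccal
ANWT01	ANW	case	73	Caucasian	buccal
ANWT03	ANW	case	61	Caucasian	buccal
ANWT04	ANW	case	41	Caucasian	buccal
ANWT05	ANW	case	56	Caucasian	buccal
ANWT06	ANW	case	57	Caucasian	buccal
ANWT09	ANW	case	66	Caucasian	buccal
ANWT10	ANW	case	50	Caucasian	buccal
ANWT12	ANW	case	74	Caucasian	buccal
ANWT13	ANW	case	54	Caucasian	buccal
ANWT14	ANW	case	68	Caucasian	buccal
ANWT15	ANW	case	26	Caucasian	buccal
ANWT16	ANW	case	48	Caucasian	buccal
ANWT17	ANW	case	48	Native American	buccal
AH_10	AA	control	55	African American	buccal
AH_12	AA	control	52	African American	buccal
AH_13	AA	control	55	African American	buccal
AH_14	AA	control	57	African American	buccal
AH_15	AA	control	52	African American	buccal
AH_16	AA	control	58	African American	buccal
AH_17	AA	control	65	African American	buccal
AH_18	AA	control	61	African American	buccal
AH_19	AA	control	57	African American	buccal
AH_20	AA	case	55	African American	buccal
AH_22	AA	case	51	African American	buccal
AH_23	AA	case	53	African American	buccal
AH_24	AA	case	56	African American	buccal
AH_25	AA	case	58	African American	buccal
AH_26	AA	case	52	African American	buccal
AH_27	AA	case	53	African American	buccal
AH_28	AA	case	50	African American	buccal
AH_29	AA	case	51	African American	buccal
AH_30	AA	case	50	African American	buccal
AH_31	AA	case	52	African American	buccal
AH_32	AA	case	52	African American	buccal
AH_33	AA	case	63	African American	buccal
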