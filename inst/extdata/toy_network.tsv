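source	relation	target	layer
AHR	increases	AHRR	backbone
AHR	increases	NicotineMetabolism	backbone
AHR	increases	PAH_activation	backbone
AHR	increases	PhaseI_oxidation	backbone
AHRR	decreases	AHR	backbone
CAR	increases	PhaseI_oxidation	backbone
CAR	increases	PXR	backbone
NRF2	increases	GSH_synthesis	backbone
NRF2	increases	PhaseII_conjugation	backbone
OxidativeStress	increases	NRF2	backbone
PhaseI_oxidation	increases	OxidativeStress	backbone
PhaseI_oxidation	increases	PAH_activation	backbone
PhaseII_conjugation	increases	PhaseIII_transport	backbone
PXR	increases	PhaseIII_transport	backbone
AHR	increases	AHR_g01	evidence
AHR	increases	AHR_g02	evidence
AHR	increases	AHR_g03	evidence
AHR	increases	AHR_g04	evidence
AHR	decreases	AHR_g05	evidence
AHR	increases	AHR_g06	evidence
AHR	increases	AHR_g07	evidence
AHR	increases	AHR_g08	evidence
AHR	increases	AHR_g09	evidence
AHR	increases	AHR_g10	evidence
AHR	increases	AHR_g11	evidence
AHR	decreases	AHR_g12	evidence
AHR	increases	AHR_g13	evidence
AHR	increases	PhaseI_oxidation_g01	evidence
AHR	increases	PhaseII_conjugation_g01	evidence
AHR	increases	PhaseIII_transport_g01	evidence
AHRR	decreases	AHRR_g01	evidence
AHRR	decreases	AHRR_g02	evidence
AHRR	decreases	AHRR_g03	evidence
AHRR	decreases	AHRR_g04	evidence
AHRR	decreases	AHRR_g05	evidence
AHRR	decreases	AHRR_g06	evidence
AHRR	decreases	AHRR_g07	evidence
AHRR	decreases	AHRR_g08	evidence
AHRR	decreases	AHRR_g09	evidence
AHRR	decreases	AHRR_g10	evidence
AHRR	decreases	AHRR_g11	evidence
AHRR	decreases	AHRR_g12	evidence
AHRR	decreases	AHRR_g13	evidence
CAR	increases	CAR_g01	evidence
CAR	increases	CAR_g02	evidence
CAR	increases	CAR_g03	evidence
CAR	increases	CAR_g04	evidence
CAR	increases	CAR_g05	evidence
CAR	decreases	CAR_g06	evidence
CAR	increases	CAR_g07	evidence
CAR	increases	CAR_g08	evidence
CAR	increases	CAR_g09	evidence
CAR	increases	CAR_g10	evidence
CAR	increases	CAR_g11	evidence
CAR	increases	CAR_g12	evidence
CAR	decreases	CAR_g13	evidence
GSH_synthesis	increases	GSH_synthesis_g01	evidence
GSH_synthesis	increases	GSH_synthesis_g02	evidence
GSH_synthesis	increases	GSH_synthesis_g03	evidence
GSH_synthesis	increases	GSH_synthesis_g04	evidence
GSH_synthesis	increases	GSH_synthesis_g05	evidence
GSH_synthesis	decreases	GSH_synthesis_g06	evidence
GSH_synthesis	increases	GSH_synthesis_g07	evidence
GSH_synthesis	increases	GSH_synthesis_g08	evidence
GSH_synthesis	increases	GSH_synthesis_g09	evidence
GSH_synthesis	increases	GSH_synthesis_g10	evidence
GSH_synthesis	increases	GSH_synthesis_g11	evidence
GSH_synthesis	increases	GSH_synthesis_g12	evidence
NicotineMetabolism	increases	NicotineMetabolism_g01	evidence
NicotineMetabolism	increases	NicotineMetabolism_g02	evidence
NicotineMetabolism	decreases	NicotineMetabolism_g03	evidence
NicotineMetabolism	increases	NicotineMetabolism_g04	evidence
NicotineMetabolism	increases	NicotineMetabolism_g05	evidence
NicotineMetabolism	increases	NicotineMetabolism_g06	evidence
NicotineMetabolism	increases	NicotineMetabolism_g07	evidence
NicotineMetabolism	increases	NicotineMetabolism_g08	evidence
NicotineMetabolism	increases	NicotineMetabolism_g09	evidence
NicotineMetabolism	decreases	NicotineMetabolism_g10	evidence
NicotineMetabolism	increases	NicotineMetabolism_g11	evidence
NicotineMetabolism	increases	NicotineMetabolism_g12	evidence
NRF2	increases	NRF2_g01	evidence
NRF2	increases	NRF2_g02	evidence
NRF2	increases	NRF2_g03	evidence
NRF2	increases	NRF2_g04	evidence
NRF2	increases	NRF2_g05	evidence
NRF2	increases	NRF2_g06	evidence
NRF2	decreases	NRF2_g07	evidence
NRF2	increases	NRF2_g08	evidence
NRF2	increases	NRF2_g09	evidence
NRF2	increases	NRF2_g10	evidence
NRF2	increases	NRF2_g11	evidence
NRF2	increases	NRF2_g12	evidence
NRF2	increases	NRF2_g13	evidence
OxidativeStress	increases	OxidativeStress_g01	evidence
OxidativeStress	increases	OxidativeStress_g02	evidence
OxidativeStress	increases	OxidativeStress_g03	evidence
OxidativeStress	decreases	OxidativeStress_g04	evidence
OxidativeStress	increases	OxidativeStress_g05	evidence
OxidativeStress	increases	OxidativeStress_g06	evidence
OxidativeStress	increases	OxidativeStress_g07	evidence
OxidativeStress	increases	OxidativeStress_g08	evidence
OxidativeStress	increases	OxidativeStress_g09	evidence
OxidativeStress	increases	OxidativeStress_g10	evidence
OxidativeStress	decreases	OxidativeStress_g11	evidence
OxidativeStress	increases	OxidativeStress_g12	evidence
OxidativeStress	increases	OxidativeStress_g13	evidence
PAH_activation	increases	PAH_activation_g01	evidence
PAH_activation	increases	PAH_activation_g02	evidence
PAH_activation	increases	PAH_activation_g03	evidence
PAH_activation	increases	PAH_activation_g04	evidence
PAH_activation	increases	PAH_activation_g05	evidence
PAH_activation	increases	PAH_activation_g06	evidence
PAH_activation	decreases	PAH_activation_g07	evidence
PAH_activation	increases	PAH_activation_g08	evidence
PAH_activation	increases	PAH_activation_g09	evidence
PAH_activation	increases	PAH_activation_g10	evidence
PAH_activation	increases	PAH_activation_g11	evidence
PAH_activation	increases	PAH_activation_g12	evidence
PhaseI_oxidation	decreases	PhaseI_oxidation_g01	evidence
PhaseI_oxidation	increases	PhaseI_oxidation_g02	evidence
PhaseI_oxidation	increases	PhaseI_oxidation_g03	evidence
PhaseI_oxidation	increases	PhaseI_oxidation_g04	evidence
PhaseI_oxidation	increases	PhaseI_oxidation_g05	evidence
PhaseI_oxidation	increases	PhaseI_oxidation_g06	evidence
PhaseI_oxidation	increases	PhaseI_oxidation_g07	evidence
PhaseI_oxidation	decreases	PhaseI_oxidation_g08	evidence
PhaseI_oxidation	increases	PhaseI_oxidation_g09	evidence
PhaseI_oxidation	increases	PhaseI_oxidation_g10	evidence
PhaseI_oxidation	increases	PhaseI_oxidation_g11	evidence
PhaseI_oxidation	increases	PhaseI_oxidation_g12	evidence
PhaseII_conjugation	increases	PhaseII_conjugation_g01	evidence
PhaseII_conjugation	increases	PhaseII_conjugation_g02	evidence
PhaseII_conjugation	increases	PhaseII_conjugation_g03	evidence
PhaseII_conjugation	increases	PhaseII_conjugation_g04	evidence
PhaseII_conjugation	decreases	PhaseII_conjugation_g05	evidence
PhaseII_conjugation	increases	PhaseII_conjugation_g06	evidence
PhaseII_conjugation	increases	PhaseII_conjugation_g07	evidence
PhaseII_conjugation	increases	PhaseII_conjugation_g08	evidence
PhaseII_conjugation	increases	PhaseII_conjugation_g09	evidence
PhaseII_conjugation	increases	PhaseII_conjugation_g10	evidence
PhaseII_conjugation	increases	PhaseII_conjugation_g11	evidence
PhaseII_conjugation	decreases	PhaseII_conjugation_g12	evidence
PhaseIII_transport	increases	PhaseIII_transport_g01	evidence
PhaseIII_transport	decreases	PhaseIII_transport_g02	evidence
PhaseIII_transport	increases	PhaseIII_transport_g03	evidence
PhaseIII_transport	increases	PhaseIII_transport_g04	evidence
PhaseIII_transport	increases	PhaseIII_transport_g05	evidence
PhaseIII_transport	increases	PhaseIII_transport_g06	evidence
PhaseIII_transport	increases	PhaseIII_transport_g07	evidence
PhaseIII_transport	increases	PhaseIII_transport_g08	evidence
PhaseIII_transport	decreases	PhaseIII_transport_g09	evidence
PhaseIII_transport	increases	PhaseIII_transport_g10	evidence
PhaseIII_transport	increases	PhaseIII_transport_g11	evidence
PhaseIII_transport	increases	PhaseIII_transport_g12	evidence
PXR	increases	PXR_g01	evidence
PXR	increases	PXR_g02	evidence
PXR	decreases	PXR_g03	evidence
PXR	increases	PXR_g04	evidence
PXR	increases	PXR_g05	evidence
PXR	increases	PXR_g06	evidence
PXR	increases	PXR_g07	evidence
PXR	increases	PXR_g08	evidence
PXR	increases	PXR_g09	evidence
PXR	decreases	PXR_g10	evidence
PXR	increases	PXR_g11	evidence
PXR	increases	PXR_g12	evidence
PXR	increases	PXR_g13	evidence
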