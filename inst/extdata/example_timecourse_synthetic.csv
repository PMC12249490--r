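protein_id,peptide_sequence,time_days,i0,i0_natural
CH60_SYNTH,ALMLQGVDLLADAVAVTMGPK,0,0.28122,0.27977
CH60_SYNTH,ALMLQGVDLLADAVAVTMGPK,1,0.252,0.27977
CH60_SYNTH,ALMLQGVDLLADAVAVTMGPK,3,0.2054,0.27977
CH60_SYNTH,ALMLQGVDLLADAVAVTMGPK,5,0.1742,0.27977
CH60_SYNTH,ALMLQGVDLLADAVAVTMGPK,7,0.14738,0.27977
CH60_SYNTH,ALMLQGVDLLADAVAVTMGPK,14,0.10072,0.27977
CH60_SYNTH,ALMLQGVDLLADAVAVTMGPK,21,0.08569,0.27977
CH60_SYNTH,VGEVIVTK,0,0.62021,0.61956
CH60_SYNTH,VGEVIVTK,1,0.60107,0.61956
CH60_SYNTH,VGEVIVTK,3,0.57492,0.61956
CH60_SYNTH,VGEVIVTK,5,0.54981,0.61956
CH60_SYNTH,VGEVIVTK,7,0.5304,0.61956
CH60_SYNTH,VGEVIVTK,14,0.48599,0.61956
CH60_SYNTH,VGEVIVTK,21,0.45598,0.61956
CH60_SYNTH,TVIIEQSWGSPK,0,0.46301,0.4638
CH60_SYNTH,TVIIEQSWGSPK,1,0.43934,0.4638
CH60_SYNTH,TVIIEQSWGSPK,3,0.39045,0.4638
CH60_SYNTH,TVIIEQSWGSPK,5,0.35658,0.4638
CH60_SYNTH,TVIIEQSWGSPK,7,0.3267,0.4638
CH60_SYNTH,TVIIEQSWGSPK,14,0.26655,0.4638
CH60_SYNTH,TVIIEQSWGSPK,21,0.23398,0.4638
CH60_SYNTH,AAVEEGIVLGGGCALLR,0,0.38773,0.38871
CH60_SYNTH,AAVEEGIVLGGGCALLR,1,0.35048,0.38871
CH60_SYNTH,AAVEEGIVLGGGCALLR,3,0.28927,0.38871
CH60_SYNTH,AAVEEGIVLGGGCALLR,5,0.24426,0.38871
CH60_SYNTH,AAVEEGIVLGGGCALLR,7,0.21182,0.38871
CH60_SYNTH,AAVEEGIVLGGGCALLR,14,0.14576,0.38871
CH60_SYNTH,AAVEEGIVLGGGCALLR,21,0.11404,0.38871
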