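study_id	modality	n_pd	n_control	updrs_off_mean	updrs_on_mean	age_pd	age_control	n_foci	contrast_label	task	reports_a_gt_b	reports_b_gt_a
Baglio2011	fMRI	15	11		21.5	66.5	66.9	6	HC vs ON	Button press with right index finger	TRUE	FALSE
Buhmann2003	fMRI	8				54		2	ON vs OFF	Random finger opposition task at 0.33 Hz with right and left hands	FALSE	TRUE
Burciu2015	fMRI	20	20	31.9		65.8	64.8	20	HC vs OFF	Grip force task with or without feedback with more affected hand	TRUE	TRUE
Caproni2013	fMRI	11	11	20		65	65.1	7	HC vs OFF	Tapping with right index finger	TRUE	TRUE
Caproni2013	fMRI	11	11	20		65	65.1	15	HC vs OFF	Sequence from dig I to V with right hand	TRUE	TRUE
Caproni2013	fMRI	11	11	20		65	65.1	13	HC vs OFF	Sequence with order dig I, III, V, II, IV with right hand	TRUE	TRUE
Cerasa2006	fMRI	10	11	27.5		64.2	63.4	8	HC vs OFF	Synchronized tapping with right index finger at 1.33 Hz	TRUE	TRUE
Cerasa2006	fMRI	10	11	27.5		64.2	63.4	3	HC vs OFF	Continuation of the tapping with right index finger without stimulus	FALSE	TRUE
Drucker2019	fMRI	22	19	33.9		67.7	64.7	4	HC vs OFF	Externally cued foot-tapping sequence	TRUE	FALSE
Drucker2019	fMRI	22	19	33.9		67.7	64.7	6	HC vs OFF	Internally cued foot-tapping sequence	TRUE	FALSE
Eckert2006	fMRI	9	9	20.6	10.7	63.3	60.6	18	HC vs OFF	Opening and closing of right fist at ~1 Hz	TRUE	TRUE
Eckert2006	fMRI	9	9	20.6	10.7	63.3	60.6	9	HC vs ON	Opening and closing of right fist at ~1 Hz	TRUE	TRUE
Eckert2006	fMRI	9		20.6	10.7	63.3		4	ON vs OFF	Opening and closing of right fist at ~1 Hz	TRUE	FALSE
GonzalezGarcia2011	fMRI	17	10		41	64.4		8	HC vs ON	Button presses with right and left hands in predefined order	TRUE	FALSE
GonzalezGarcia2011	fMRI	17	10		41	64.4		5	HC vs ON	Button presses with right and left hands in random order	TRUE	FALSE
Haslinger2001	fMRI	8	8	15.8	11.8	60.8	54.4	7	HC vs OFF	Joystick movements with right hand with 4 spatial dof	TRUE	TRUE
Haslinger2001	fMRI	8	8	15.8	11.8	60.8	54.4	8	HC vs ON	Joystick movements with right hand with 4 spatial dof	TRUE	FALSE
Haslinger2001	fMRI	8		15.8	11.8	60.8		10	ON vs OFF	Joystick movements with right hand with 4 spatial dof	TRUE	TRUE
Holiga2012	fMRI	12		33.5	9.6	56		5	ON vs OFF	Index-to-thumb opposition movements with right and left hands at 1 Hz	TRUE	FALSE
Hughes2010	fMRI	16	15	31.3	18.9	63.9	66.5	10	HC vs ON	Specified and chosen button presses with right hand	TRUE	TRUE
Jia2018	fMRI	22	22	16.45		61	60.6	8	HC vs OFF	Self-initiated tapping with right index finger at approximately 0.5 Hz	TRUE	TRUE
Katschnig2011	fMRI	20	20	37.9		66.8	62.3	2	HC vs OFF	Dorsiflexion of right and left ankles at 1 Hz	FALSE	TRUE
Kim2018	fMRI	16	15	36		63.1	64.1	6	HC vs OFF	Two-choice forced response task with fingers II and III of right hand	TRUE	FALSE
Kim2018	fMRI	16	15	36		63.1	64.1	19	HC vs ON	Two-choice forced response task with fingers II and III of right hand	TRUE	TRUE
Kim2018	fMRI	16		36		63.1		5	ON vs OFF	Two-choice forced response task with fingers II and III of right hand	TRUE	FALSE
Kraft2009	fMRI	12	12	21	13.9	60.8	53	12	HC vs OFF	Grip-force task with right and left hands simultaneously	TRUE	TRUE
Kraft2009	fMRI	12	12	21	13.9	60.8	53	8	HC vs ON	Grip-force task with right and left hands simultaneously	TRUE	TRUE
Kraft2009	fMRI	12		21	13.9	60.8		4	ON vs OFF	Grip-force task with right and left hands simultaneously	TRUE	FALSE
Kraft2009	fMRI	12	12	21	13.9	60.8	53	13	HC vs OFF	Grip-force task with right and left hands alternating	TRUE	TRUE
Kraft2009	fMRI	12	12	21	13.9	60.8	53	4	HC vs ON	Grip-force task with right and left hands alternating	TRUE	FALSE
Kraft2009	fMRI	12		21	13.9	60.8		4	ON vs OFF	Grip-force task with right and left hands alternating	TRUE	FALSE
Maillet2012	fMRI	12		40.3	10	59.8		2	ON vs OFF	Joystick movements with right hand with 4 spatial dof at 0.5 Hz	TRUE	FALSE
Mak2016	fMRI	26	21		29	61.4	60.9	3	HC vs ON	Self-initiated index finger tapping at ~0.2-0.3 Hz on most affected side	TRUE	FALSE
Mak2016	fMRI	26	21		29	61.4	60.9	3	HC vs ON	Cued index finger tapping at ~0.2-0.3 Hz on most affected side	TRUE	FALSE
Mallol2007	fMRI	13	11	22.6		64.9	61.9	13	HC vs OFF	Finger-to-thumb opposition and rotating movements of right hand	TRUE	TRUE
Martin2019	fMRI	22	22	15.6		53	48.5	13	HC vs OFF	Self-generated sequential button press with fingers I-IV of most affected hand	TRUE	TRUE
Martin2019	fMRI	22	22	15.6		53	48.5	10	HC vs OFF	Self-generated sequential button press with fingers I-IV of less affected hand	TRUE	TRUE
Martin2019	fMRI	22	22	15.6		53	48.5	13	HC vs OFF	Visually-cued sequential button press with fingers I-IV of most affected hand	TRUE	TRUE
Martin2019	fMRI	22	22	15.6		53	48.5	5	HC vs OFF	Visually-cued sequential button press with fingers I-IV of less affected hand	TRUE	FALSE
Mattay2002	fMRI	7		8.8	5	55		7	ON vs OFF	Button presses with right hand (0-back task)	TRUE	TRUE
Mohl2017	fMRI	26	21	33	24	62.2	61.6	1	HC vs OFF	1 Hz sequential tapping from fingers I-V and vice versa with right hand	FALSE	TRUE
Payoux2011	PET	8	10	22	12	62	67	3	HC vs OFF	Joystick movements with right hand with 4 spatial dof at 0.33 Hz	FALSE	TRUE
Payoux2011	PET	8		22	12	62		1	ON vs OFF	Joystick movements with right hand with 4 spatial dof at 0.33 Hz	FALSE	TRUE
Pinto2011	fMRI	9	15	33		59	55	6	HC vs OFF	Joystick movements with right hand with 4 spatial dof at 0.5 Hz	TRUE	TRUE
Planetta2015	fMRI	14	14	29.6		64	61.9	34	HC vs OFF	Cued and memorized pinch grip force task with most affected hand (collapsed)	TRUE	TRUE
Poisson2013	fMRI	6	10	16		65	53.6	13	HC vs OFF	Finger-thumb tapping with right hand at 1 Hz	TRUE	TRUE
Rottschy2013	fMRI	23	23		23.9	67.2	65	8	HC vs ON	Direct repeat of sequence of 4 or 5 finger movements with both hands	TRUE	TRUE
Rottschy2013	fMRI	23	23		23.9	67.2	65	14	HC vs ON	Delayed repeat of sequence of 4 or 5 finger movements with both hands	TRUE	TRUE
Rowe2002	fMRI	12	12	33.7		62	62	2	HC vs OFF	Sequential finger movements of right hand at 0.33 Hz	FALSE	TRUE
Sabatini2000	fMRI	6	6	16		61	59	15	HC vs OFF	Finger-to-thumb opposition movements and fist clenching with right hand	TRUE	TRUE
Samuel1997	PET	6	6	17.7		70.2	64.3	7	HC vs OFF	Sequential finger movements of right hand at 0.33 Hz	TRUE	TRUE
Samuel1997	PET	6	6	17.7		70.2	64.3	10	HC vs OFF	Bimanual sequential finger movements at 0.33 Hz	TRUE	TRUE
Tessa2010	fMRI	15	11	16.1		70.1	69	12	HC vs OFF	Continuous tapping of right hand	TRUE	TRUE
Tessa2012	fMRI	15	13	16.3		68.1	64.2	4	HC vs OFF	Continuous writing of the figure 8 with right hand	TRUE	FALSE
Tessa2013	fMRI	11	10	13.5		67.7	64	6	HC vs OFF	Continuous tapping of left hand	TRUE	TRUE
Turner2003	PET	12	12	41.4		57	58	9	HC vs OFF	Tracking task with right hand	TRUE	TRUE
Wu2005	fMRI	12	12	25.5		61.2	61.8	12	HC vs OFF	Sequential finger tapping with right hand at ~0.5 Hz	TRUE	TRUE
Wu2010	fMRI	15	15	20.7		59.7	60.3	15	HC vs OFF	In-phase movements of both index fingers at ~0.5 Hz	TRUE	TRUE
Wu2010	fMRI	15	15	20.7		59.7	60.3	20	HC vs OFF	Antiphase movements of both index fingers at ~0.5 Hz	TRUE	TRUE
Wu2015	fMRI	26	26	13		59	58.9	7	HC vs OFF	Tapping with right index finger at 0.3-0.5 Hz	TRUE	TRUE
Wu2016	fMRI	18	18	20.4		60.4	59.9	11	HC vs OFF	Free writing, consistent micrographia	TRUE	TRUE
Wu2016	fMRI	18		20.4		60.4		7	ON vs OFF	Free writing, consistent micrographia	TRUE	TRUE
Wu2016	fMRI	18	18	19.1		59.6	60	9	HC vs OFF	Free writing, progressive micrographia	TRUE	TRUE
Wu2016	fMRI	18		19.1		59.6		4	ON vs OFF	Free writing, progressive micrographia	TRUE	FALSE
Wurster2015	fMRI	10	10		20.7	66.4	64.9	2	HC vs ON	Auditory-cued button press with right index finger at 1, 2.5, and 4 Hz (collapsed)	FALSE	TRUE
Yan2015	fMRI	11	12	20.1		61.5	65.5	5	HC vs OFF	Auditory-cued finger-to-thumb movement with left hand	TRUE	FALSE
Yan2015	fMRI	11	12	20.1		61.5	65.5	4	HC vs OFF	Auditory-cued finger-to-thumb movement with right hand	TRUE	FALSE
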