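scale	subscale	level	n	mean_pref	p_printed
ABI	Core ASD symptom scale score	mild	39	53.7	0.02
ABI	Core ASD symptom scale score	moderate	39	54.8	<1e-4
ABI	Core ASD symptom scale score	severe	39	54.2	0.01
ABI	Challenging behavior	mild	39	52.4	0.12
ABI	Challenging behavior	moderate	39	55.1	<1e-3
ABI	Challenging behavior	severe	39	55.4	<1e-4
ABI	Mental health	mild	39	52.3	0.06
ABI	Mental health	moderate	39	54.4	<1e-3
ABI	Mental health	severe	39	56.1	<1e-4
ABI	Restrictive repetitive behaviors	mild	39	52.9	0.05
ABI	Restrictive repetitive behaviors	moderate	39	53.7	0.01
ABI	Restrictive repetitive behaviors	severe	39	56.2	<1e-4
ABI	Self-regulation	mild	39	52.5	0.15
ABI	Self-regulation	moderate	39	54.4	<1e-3
ABI	Self-regulation	severe	39	55.8	<1e-4
ABI	Social communication	mild	39	54.6	0.01
ABI	Social communication	moderate	39	54.5	<1e-3
ABI	Social communication	severe	39	53.6	0.01
ADOS-2	Restricted and repetitive behavior	mild	40	53.8	0.01
ADOS-2	Restricted and repetitive behavior	moderate	40	54.4	0.01
ADOS-2	Restricted and repetitive behavior	severe	41	55.2	<1e-4
ADOS-2	Social affect	mild	40	54.9	0.01
ADOS-2	Social affect	moderate	40	55.2	<1e-4
ADOS-2	Social affect	severe	41	53.3	0.01
ADOS-2	Total score	mild	40	56.0	<1e-4
ADOS-2	Total score	moderate	40	53.2	0.05
ADOS-2	Total score	severe	41	54.2	<1e-3
ABC	Hyperactivity non-compliance	mild	40	53.2	0.02
ABC	Hyperactivity non-compliance	moderate	40	54.7	0.01
ABC	Hyperactivity non-compliance	severe	41	55.5	<1e-4
ABC	Inappropriate speech	mild	40	53.3	0.05
ABC	Inappropriate speech	moderate	40	53.9	<1e-3
ABC	Inappropriate speech	severe	41	56.1	<1e-4
ABC	Irritability	mild	40	51.7	0.08
ABC	Irritability	moderate	40	56.2	<1e-4
ABC	Irritability	severe	41	55.4	<1e-4
ABC	Lethargy social withdrawal	mild	40	55.8	<1e-5
ABC	Lethargy social withdrawal	moderate	40	53.6	0.02
ABC	Lethargy social withdrawal	severe	41	54.0	0.01
ABC	Stereotypic behavior	mild	40	53.6	0.03
ABC	Stereotypic behavior	moderate	40	53.6	0.01
ABC	Stereotypic behavior	severe	41	56.2	<1e-5
CASI-Anx	Total score	mild	40	54.9	0.01
CASI-Anx	Total score	moderate	40	54.2	0.01
CASI-Anx	Total score	severe	41	54.4	<1e-3
RBS-R	Compulsive behavior	mild	40	53.0	0.03
RBS-R	Compulsive behavior	moderate	40	55.7	<1e-3
RBS-R	Compulsive behavior	severe	41	54.7	<1e-3
RBS-R	Ritualistic behavior	mild	40	52.5	0.11
RBS-R	Ritualistic behavior	moderate	40	54.4	<1e-3
RBS-R	Ritualistic behavior	severe	41	56.4	<1e-5
RBS-R	Restricted behavior	mild	40	53.7	0.01
RBS-R	Restricted behavior	moderate	40	53.8	0.01
RBS-R	Restricted behavior	severe	41	55.9	<1e-4
RBS-R	Sameness behavior	mild	40	52.8	0.08
RBS-R	Sameness behavior	moderate	40	54.5	<1e-3
RBS-R	Sameness behavior	severe	41	56.1	<1e-4
RBS-R	Self-injurious behavior	mild	40	53.1	0.02
RBS-R	Self-injurious behavior	moderate	40	54.2	0.02
RBS-R	Self-injurious behavior	severe	41	56.1	<1e-6
RBS-R	Stereotyped behavior	mild	40	54.5	0.01
RBS-R	Stereotyped behavior	moderate	40	52.8	0.02
RBS-R	Stereotyped behavior	severe	41	56.1	<1e-5
RBS-R	Total score	mild	40	52.4	0.15
RBS-R	Total score	moderate	40	54.5	<1e-3
RBS-R	Total score	severe	41	56.5	<1e-5
SRS-2	Social awareness	mild	40	54.2	<1e-3
SRS-2	Social awareness	moderate	40	53.8	0.01
SRS-2	Social awareness	severe	40	55.1	<1e-3
SRS-2	Social cognition	mild	40	53.2	0.01
SRS-2	Social cognition	moderate	40	53.8	0.01
SRS-2	Social cognition	severe	40	56.2	<1e-4
SRS-2	Social communication	mild	40	54.0	0.01
SRS-2	Social communication	moderate	40	54.4	<1e-3
SRS-2	Social communication	severe	40	54.7	<1e-3
SRS-2	Social motivation	mild	40	55.2	<1e-3
SRS-2	Social motivation	moderate	40	53.6	0.01
SRS-2	Social motivation	severe	40	54.3	<1e-3
SRS-2	Restricted interests and repetitive behavior	mild	40	52.5	0.04
SRS-2	Restricted interests and repetitive behavior	moderate	40	54.7	<1e-3
SRS-2	Restricted interests and repetitive behavior	severe	40	55.9	<1e-4
SRS-2	Social communication and interaction	mild	40	53.1	0.01
SRS-2	Social communication and interaction	moderate	40	54.6	0.01
SRS-2	Social communication and interaction	severe	40	55.4	<1e-4
SRS-2	Total score	mild	40	53.0	0.02
SRS-2	Total score	moderate	40	54.3	0.01
SRS-2	Total score	severe	40	55.8	<1e-4
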