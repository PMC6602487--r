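# Starter NegEx trigger lexicon: phrase<TAB>category<TAB>max_scope
# max_scope is a token window for PRE_NEG/POST_NEG; empty = sentence bound.
no	PRE_NEG	5
not	PRE_NEG	5
without	PRE_NEG	5
denies	PRE_NEG	5
denied	PRE_NEG	5
deny	PRE_NEG	5
absence of	PRE_NEG	5
lack of	PRE_NEG	5
lacks	PRE_NEG	5
negative for	PRE_NEG	5
no evidence of	PRE_NEG	5
no sign of	PRE_NEG	5
no signs of	PRE_NEG	5
no history of	PRE_NEG	5
free of	PRE_NEG	5
never had	PRE_NEG	5
never developed	PRE_NEG	5
rules out	PRE_NEG	5
ruled out	PRE_NEG	5
fails to reveal	PRE_NEG	5
cannot see	PRE_NEG	5
unremarkable for	PRE_NEG	5
unlikely	POST_NEG	5
was ruled out	POST_NEG	5
is ruled out	POST_NEG	5
were ruled out	POST_NEG	5
was absent	POST_NEG	5
is absent	POST_NEG	5
has resolved	POST_NEG	5
was not seen	POST_NEG	5
no increase	PSEUDO_NEG
no change	PSEUDO_NEG
no significant change	PSEUDO_NEG
no further	PSEUDO_NEG
not only	PSEUDO_NEG
not certain if	PSEUDO_NEG
not certain whether	PSEUDO_NEG
gram negative	PSEUDO_NEG
not ruled out	PSEUDO_NEG
but	TERMINATION
however	TERMINATION
although	TERMINATION
though	TERMINATION
except	TERMINATION
aside from	TERMINATION
apart from	TERMINATION
nevertheless	TERMINATION
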