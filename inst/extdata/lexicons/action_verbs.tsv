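activate	activate|activates|activated|activating|activation|activator
bind	bind|binds|bound|binding|binder
block	block|blocks|blocked|blocking|blocker
depend	depend|depends|depended|depending|dependent|dependence
express	express|expresses|expressed|expressing|expression
interact	interact|interacts|interacted|interacting|interaction|interactions|interactor
induce	induce|induces|induced|inducing|induction|inducer
inhibit	inhibit|inhibits|inhibited|inhibiting|inhibition|inhibitor
cause	cause|causes|caused|causing
phosphorylate	phosphorylate|phosphorylates|phosphorylated|phosphorylating|phosphorylation
regulate	regulate|regulates|regulated|regulating|regulation|regulator
associate	associate|associates|associated|associating|association
recruit	recruit|recruits|recruited|recruiting|recruitment
suppress	suppress|suppresses|suppressed|suppressing|suppression|suppressor
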